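# Reading and writing reaction networks.
#
# Native format: one UTF-8 tab-separated file with [species], [reactions] and
# [parameters] sections. Reaction sides use the usual "2 A + B" syntax. Rate
# constant fields may be numeric literals or parameter symbols (also products
# like "k1*Etot").
#
# SBML: a mass-action subset of Level 2/3. Kinetic laws must be products of a
# constant and reactant concentrations matching the stoichiometry (minus the
# symmetric backward product for reversible reactions); anything else fails
# loudly, naming the reaction.

#' Load a reaction network from a file
#'
#' @param path file path.
#' @param format \code{"native"} or \code{"sbml"} (guessed from the extension
#'   by default).
#' @return a \code{crn}.
#' @export
load_network <- function(path, format = c("auto", "native", "sbml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "native"
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format, native = read_crn_native(path), sbml = read_crn_sbml(path))
}

#' Parse a reaction side like "2 A + B"
#' @keywords internal
parse_side <- function(s) {
  s <- trimws(s)
  if (s == "" || s == "0") return(stats::setNames(integer(0), character(0)))
  parts <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
  out <- integer(0)
  for (p in parts) {
    m <- regmatches(p, regexec("^([0-9]+)?\\s*(\\S+)$", p))[[1]]
    if (length(m) == 0) stop("cannot parse reaction side: ", s)
    k <- if (m[2] == "") 1L else as.integer(m[2])
    sp <- m[3]
    out[sp] <- (if (sp %in% names(out)) out[[sp]] else 0L) + k
  }
  out
}

.format_k <- function(value, par) {
  if (is.null(par)) return(format(value, digits = 17))
  paste(ifelse(par == 1, names(par), paste0(names(par), "^", par)), collapse = "*")
}

.parse_k_field <- function(s, parameters) {
  s <- trimws(s)
  if (s == "" || s == "0") return(0)
  if (grepl("^[0-9.eE+-]+$", s) && !is.na(suppressWarnings(as.numeric(s))))
    return(as.numeric(s))
  factors <- trimws(strsplit(s, "*", fixed = TRUE)[[1]])
  par <- numeric(0)
  for (f in factors) {
    m <- regmatches(f, regexec("^([^^]+)(\\^(-?[0-9]+))?$", f))[[1]]
    sym <- trimws(m[2]); e <- if (m[4] == "") 1 else as.numeric(m[4])
    par[sym] <- (if (sym %in% names(par)) par[[sym]] else 0) + e
  }
  par
}

#' Write a network in the native tab-separated format
#'
#' @param net a \code{crn}.
#' @param path output file path.
#' @export
write_crn_native <- function(net, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(paste(..., sep = "\t"), con)
  writeLines("# crnreduce network v1", con)
  writeLines("[species]", con)
  w("id", "name", "initial", "compartment")
  for (i in seq_len(n_species(net))) {
    s <- net$species[i, ]
    w(s$id, s$name, format(s$initial, digits = 17), ifelse(is.na(s$compartment), "", s$compartment))
  }
  writeLines("[reactions]", con)
  w("id", "reactants", "products", "k_forward", "k_backward")
  for (rx in net$reactions) {
    w(rx$id, .format_side(rx$reactants), .format_side(rx$products),
      .format_k(rx$kf, rx$kf_par),
      if (!rx$reversible && is.null(rx$kr_par)) "0" else .format_k(rx$kr, rx$kr_par))
  }
  writeLines("[parameters]", con)
  w("symbol", "value")
  for (nm in names(net$parameters)) w(nm, format(net$parameters[[nm]], digits = 17))
  invisible(path)
}

#' Read a network from the native format
#'
#' @param path file path.
#' @return a \code{crn}.
#' @export
read_crn_native <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines)]
  sec <- NULL
  rows <- list(species = list(), reactions = list(), parameters = list())
  header <- list()
  for (ln in lines) {
    if (trimws(ln) == "") next
    if (grepl("^\\[", ln)) { sec <- gsub("[][]", "", trimws(ln)); next }
    if (is.null(sec)) stop("malformed native file: content before first section")
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (is.null(header[[sec]])) { header[[sec]] <- f; next }
    rows[[sec]][[length(rows[[sec]]) + 1L]] <- f
  }
  pars <- numeric(0)
  for (r in rows$parameters) pars[r[1]] <- as.numeric(r[2])
  sp <- if (length(rows$species) == 0)
    species_table(character(0))
  else {
    m <- do.call(rbind, lapply(rows$species, function(r) { length(r) <- 4; r }))
    species_table(id = m[, 1], name = m[, 2], initial = as.numeric(m[, 3]),
                  compartment = ifelse(is.na(m[, 4]) | m[, 4] == "", NA_character_, m[, 4]))
  }
  rxns <- lapply(rows$reactions, function(r) {
    reaction(id = r[1], reactants = parse_side(r[2]), products = parse_side(r[3]),
             kf = .parse_k_field(r[4], pars), kr = .parse_k_field(r[5], pars))
  })
  crn(sp, rxns, pars)
}

## ---- SBML --------------------------------------------------------------

# Flatten a MathML expression into a product decomposition:
# list(coef = numeric, sym = named exponent vector), or NULL if not a product.
.mathml_product <- function(node, ns) {
  nm <- xml2::xml_name(node)
  if (nm == "ci") {
    return(list(coef = 1, sym = stats::setNames(1, trimws(xml2::xml_text(node)))))
  }
  if (nm == "cn") {
    return(list(coef = as.numeric(xml2::xml_text(node)), sym = numeric(0)))
  }
  if (nm != "apply") return(NULL)
  ch <- xml2::xml_children(node)
  op <- xml2::xml_name(ch[[1]])
  args <- ch[-1]
  if (op == "times") {
    coef <- 1; sym <- numeric(0)
    for (a in args) {
      p <- .mathml_product(a, ns)
      if (is.null(p)) return(NULL)
      coef <- coef * p$coef
      for (s in names(p$sym)) sym[s] <- (if (s %in% names(sym)) sym[[s]] else 0) + p$sym[[s]]
    }
    return(list(coef = coef, sym = sym))
  }
  if (op == "power") {
    b <- .mathml_product(args[[1]], ns)
    e <- as.numeric(xml2::xml_text(args[[2]]))
    if (is.null(b) || length(b$sym) != 1 || b$coef != 1) return(NULL)
    return(list(coef = 1, sym = b$sym * e))
  }
  NULL
}

# Decompose kinetic math into one or two (forward/backward) products.
.mathml_kinetic <- function(mathnode, ns) {
  ch <- xml2::xml_children(mathnode)
  if (length(ch) != 1) return(NULL)
  node <- ch[[1]]
  p <- .mathml_product(node, ns)
  if (!is.null(p)) return(list(forward = p, backward = NULL))
  if (xml2::xml_name(node) == "apply") {
    kids <- xml2::xml_children(node)
    if (xml2::xml_name(kids[[1]]) == "minus" && length(kids) == 3) {
      f <- .mathml_product(kids[[2]], ns)
      b <- .mathml_product(kids[[3]], ns)
      if (!is.null(f) && !is.null(b)) return(list(forward = f, backward = b))
    }
  }
  NULL
}

#' Read a mass-action SBML model
#'
#' Supports the mass-action subset of SBML Level 2/3: kinetic laws must be a
#' product \code{k * prod(reactants^stoich)}, optionally minus the symmetric
#' backward product for reversible reactions. Compartment factors of volume 1
#' are tolerated. Any other kinetic law raises an error naming the reaction.
#'
#' @param path SBML file path.
#' @return a \code{crn}.
#' @export
read_crn_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing")) stop("malformed SBML: no <model> element")

  comp_nodes <- xml2::xml_find_all(model, ".//listOfCompartments/compartment")
  comp_size <- stats::setNames(
    vapply(comp_nodes, function(n) {
      s <- xml2::xml_attr(n, "size")
      if (is.na(s)) 1 else as.numeric(s)
    }, 0),
    xml2::xml_attr(comp_nodes, "id"))

  sp_nodes <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  ids <- xml2::xml_attr(sp_nodes, "id")
  init <- vapply(sp_nodes, function(n) {
    v <- xml2::xml_attr(n, "initialConcentration")
    if (is.na(v)) v <- xml2::xml_attr(n, "initialAmount")
    if (is.na(v)) 0 else as.numeric(v)
  }, 0)
  nm <- xml2::xml_attr(sp_nodes, "name"); nm[is.na(nm)] <- ids[is.na(nm)]
  comp <- xml2::xml_attr(sp_nodes, "compartment")
  sp <- species_table(ids, nm, init, comp)

  par_nodes <- xml2::xml_find_all(model, ".//listOfParameters/parameter")
  pars <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                          xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  rxns <- list()
  for (rn in rx_nodes) {
    rid <- xml2::xml_attr(rn, "id")
    rev <- identical(xml2::xml_attr(rn, "reversible"), "true")
    get_side <- function(tag) {
      refs <- xml2::xml_find_all(rn, paste0("./", tag, "/speciesReference"))
      s <- integer(0)
      for (ref in refs) {
        spid <- xml2::xml_attr(ref, "species")
        st <- xml2::xml_attr(ref, "stoichiometry")
        st <- if (is.na(st)) 1L else as.integer(as.numeric(st))
        s[spid] <- (if (spid %in% names(s)) s[[spid]] else 0L) + st
      }
      s
    }
    reac <- get_side("listOfReactants")
    prod_ <- get_side("listOfProducts")
    kl <- xml2::xml_find_first(rn, "./kineticLaw")
    if (inherits(kl, "xml_missing")) stop("reaction ", rid, ": missing kinetic law")
    loc_nodes <- xml2::xml_find_all(kl, ".//parameter|.//localParameter")
    loc <- stats::setNames(as.numeric(xml2::xml_attr(loc_nodes, "value")),
                           xml2::xml_attr(loc_nodes, "id"))
    # local parameters are renamed reactionid_name to keep the global map flat
    if (length(loc)) {
      names(loc) <- paste0(rid, "_", names(loc))
    }
    allpars <- c(pars, loc)
    math <- xml2::xml_find_first(kl, "./math")
    dec <- if (!inherits(math, "xml_missing")) .mathml_kinetic(math, NULL) else NULL
    if (is.null(dec))
      stop("unsupported kinetics in reaction ", rid,
           ": only mass-action products are accepted")
    classify <- function(prodpart, stoich, what) {
      sym <- prodpart$sym
      kpar <- numeric(0)
      spexp <- numeric(0)
      for (s in names(sym)) {
        if (s %in% ids) spexp[s] <- sym[[s]]
        else if (s %in% names(allpars)) kpar[s] <- sym[[s]]
        else if (s %in% names(loc) || paste0(rid, "_", s) %in% names(loc))
          kpar[paste0(rid, "_", s)] <- sym[[s]]
        else if (s %in% names(comp_size)) {
          if (abs(comp_size[[s]] - 1) > 0) stop("reaction ", rid,
            ": non-unit compartment volume in kinetic law is not supported")
        } else stop("reaction ", rid, ": unknown symbol ", s, " in kinetic law")
      }
      want <- stoich[stoich != 0]
      have <- spexp[spexp != 0]
      if (!identical(sort(names(want)), sort(names(have))) ||
          !all(want[sort(names(want))] == have[sort(names(have))]))
        stop("unsupported kinetics in reaction ", rid, ": ", what,
             " rate is not mass-action for its stoichiometry")
      kpar
    }
    kf_par <- classify(dec$forward, reac, "forward")
    kf_coef <- dec$forward$coef
    kr <- 0; kr_par <- NULL
    if (!is.null(dec$backward)) {
      if (!rev) stop("reaction ", rid, ": backward term in an irreversible reaction")
      kr_par <- classify(dec$backward, prod_, "backward")
      kr_coef <- dec$backward$coef
      if (kr_coef != 1) {
        allpars[paste0(rid, "_krnum")] <- kr_coef
        kr_par <- c(kr_par, stats::setNames(1, paste0(rid, "_krnum")))
      }
      kr <- kr_par
    }
    if (kf_coef != 1) {
      allpars[paste0(rid, "_kfnum")] <- kf_coef
      kf_par <- c(kf_par, stats::setNames(1, paste0(rid, "_kfnum")))
    }
    if (length(kf_par) == 0) stop("reaction ", rid, ": no rate constant in kinetic law")
    pars <- allpars
    rxns[[length(rxns) + 1L]] <- reaction(rid, reac, prod_,
                                          kf = kf_par,
                                          kr = if (is.null(kr_par)) 0 else kr_par)
  }
  crn(sp, rxns, pars[!is.na(pars)])
}

#' Write a mass-action network as SBML Level 2
#'
#' @param net a \code{crn}.
#' @param path output path.
#' @export
write_crn_sbml <- function(net, path) {
  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level2/version4", level = "2", version = "4")
  model <- xml2::xml_add_child(doc, "model", id = "model")
  lc <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(lc, "compartment", id = "cell", size = "1")
  ls_ <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(n_species(net))) {
    s <- net$species[i, ]
    xml2::xml_add_child(ls_, "species", id = s$id, name = s$name,
                        compartment = if (is.na(s$compartment)) "cell" else s$compartment,
                        initialConcentration = format(s$initial, digits = 17))
  }
  lp <- xml2::xml_add_child(model, "listOfParameters")
  for (nm in names(net$parameters))
    xml2::xml_add_child(lp, "parameter", id = nm,
                        value = format(net$parameters[[nm]], digits = 17))
  lr <- xml2::xml_add_child(model, "listOfReactions")
  for (rx in net$reactions) {
    rn <- xml2::xml_add_child(lr, "reaction", id = rx$id,
                              reversible = tolower(as.character(rx$reversible)))
    add_side <- function(tag, side) {
      if (length(side) == 0) return()
      l <- xml2::xml_add_child(rn, tag)
      for (sp in names(side))
        xml2::xml_add_child(l, "speciesReference", species = sp,
                            stoichiometry = as.character(side[[sp]]))
    }
    add_side("listOfReactants", rx$reactants)
    add_side("listOfProducts", rx$products)
    kl <- xml2::xml_add_child(rn, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math", xmlns = "http://www.w3.org/1998/Math/MathML")
    prod_node <- function(parent, par, value, side) {
      ap <- xml2::xml_add_child(parent, "apply")
      xml2::xml_add_child(ap, "times")
      if (is.null(par)) {
        xml2::xml_add_child(ap, "cn", format(value, digits = 17))
      } else {
        for (nm in names(par)) {
          if (par[[nm]] == 1) xml2::xml_add_child(ap, "ci", nm)
          else {
            pw <- xml2::xml_add_child(ap, "apply")
            xml2::xml_add_child(pw, "power")
            xml2::xml_add_child(pw, "ci", nm)
            xml2::xml_add_child(pw, "cn", as.character(par[[nm]]))
          }
        }
      }
      for (sp in names(side)) {
        if (side[[sp]] == 1) xml2::xml_add_child(ap, "ci", sp)
        else {
          pw <- xml2::xml_add_child(ap, "apply")
          xml2::xml_add_child(pw, "power")
          xml2::xml_add_child(pw, "ci", sp)
          xml2::xml_add_child(pw, "cn", as.character(side[[sp]]))
        }
      }
    }
    if (rx$reversible) {
      ap <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(ap, "minus")
      prod_node(ap, rx$kf_par, rx$kf, rx$reactants)
      prod_node(ap, rx$kr_par, rx$kr, rx$products)
    } else {
      prod_node(math, rx$kf_par, rx$kf, rx$reactants)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
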