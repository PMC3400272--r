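<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic SBML fixture: irreversible Michaelis-Menten mechanism,
     mass-action kinetics. Written by hand for testing the SBML reader. -->
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="mm_synthetic" name="Michaelis-Menten mechanism (synthetic)">
    <listOfCompartments>
      <compartment id="cell" size="1"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="S" name="substrate" compartment="cell" initialConcentration="10"/>
      <species id="E" name="enzyme" compartment="cell" initialConcentration="0.1"/>
      <species id="ES" name="complex" compartment="cell" initialConcentration="0"/>
      <species id="P" name="product" compartment="cell" initialConcentration="0"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="k1" value="2"/>
      <parameter id="km1" value="3"/>
      <parameter id="k2" value="5"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="binding" reversible="true">
        <listOfReactants>
          <speciesReference species="S" stoichiometry="1"/>
          <speciesReference species="E" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="ES" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply>
              <minus/>
              <apply>
                <times/>
                <ci>k1</ci>
                <ci>S</ci>
                <ci>E</ci>
              </apply>
              <apply>
                <times/>
                <ci>km1</ci>
                <ci>ES</ci>
              </apply>
            </apply>
          </math>
        </kineticLaw>
      </reaction>
      <reaction id="catalysis" reversible="false">
        <listOfReactants>
          <speciesReference species="ES" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="P" stoichiometry="1"/>
          <speciesReference species="E" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply>
              <times/>
              <ci>k2</ci>
              <ci>ES</ci>
            </apply>
          </math>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
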