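<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">
  <model id="toy_chain_l2" name="three-reaction chain (legacy dialect)">
    <listOfCompartments>
      <compartment id="c"/>
      <compartment id="e"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="M_a_e" name="substrate A (external)" compartment="e"/>
      <species id="M_a_c" name="substrate A" compartment="c"/>
      <species id="M_a_b" name="A boundary" compartment="e" boundaryCondition="true"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="R_EX_a" name="A exchange" reversible="true">
        <listOfReactants>
          <speciesReference species="M_a_e" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_a_b" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="-10"/>
            <parameter id="UPPER_BOUND" value="0"/>
            <parameter id="OBJECTIVE_COEFFICIENT" value="0"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="R_At" name="A transport" reversible="false">
        <notes>
          <body xmlns="http://www.w3.org/1999/xhtml">
            <p>GENE_ASSOCIATION: (b0001 and b0002) or b0003</p>
            <p>SUBSYSTEM: transport</p>
          </body>
        </notes>
        <listOfReactants>
          <speciesReference species="M_a_e" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_a_c" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="0"/>
            <parameter id="UPPER_BOUND" value="1000"/>
            <parameter id="OBJECTIVE_COEFFICIENT" value="0"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="R_BIOMASS" name="biomass drain" reversible="false">
        <listOfReactants>
          <speciesReference species="M_a_c" stoichiometry="1"/>
        </listOfReactants>
        <kineticLaw>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="0"/>
            <parameter id="UPPER_BOUND" value="1000"/>
            <parameter id="OBJECTIVE_COEFFICIENT" value="1"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
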