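concept	iri	label
rdf_type	http://www.w3.org/1999/02/22-rdf-syntax-ns#type	type
molecular_entity	http://purl.org/obo/owl/CHEBI#CHEBI_23367	molecular entity
molecule	http://purl.org/obo/owl/CHEBI#CHEBI_25367	molecule
organic_group	http://purl.org/obo/owl/CHEBI#CHEBI_33247	organic group
group	http://purl.org/obo/owl/CHEBI#CHEBI_33249	organic functional group
primary_alcohol	http://purl.org/obo/owl/CHEBI#CHEBI_15734	primary alcohol
atom	http://purl.org/obo/owl/CHEBI#CHEBI_33250	atom
atom_C	http://purl.org/obo/owl/CHEBI#CHEBI_27594	carbon atom
atom_O	http://purl.org/obo/owl/CHEBI#CHEBI_25805	oxygen atom
atom_H	http://purl.org/obo/owl/CHEBI#CHEBI_49637	hydrogen atom
atom_N	http://purl.org/obo/owl/CHEBI#CHEBI_25555	nitrogen atom
atom_S	http://purl.org/obo/owl/CHEBI#CHEBI_26833	sulfur atom
atom_P	http://purl.org/obo/owl/CHEBI#CHEBI_28659	phosphorus atom
covalent_bond	http://semanticscience.org/resource/SIO_011118	covalent bond
bond_single	http://semanticscience.org/resource/SIO_010498	single bond
bond_double	http://semanticscience.org/resource/CHESS_DoubleBond	double bond
bond_triple	http://semanticscience.org/resource/CHESS_TripleBond	triple bond
bond_aromatic	http://semanticscience.org/resource/CHESS_AromaticBond	aromatic bond
has_single_bond_with	http://semanticscience.org/resource/CHESS_hasSingleBondWith	has single bond with
has_double_bond_with	http://semanticscience.org/resource/CHESS_hasDoubleBondWith	has double bond with
has_triple_bond_with	http://semanticscience.org/resource/CHESS_hasTripleBondWith	has triple bond with
has_aromatic_bond_with	http://semanticscience.org/resource/CHESS_hasAromaticBondWith	has aromatic bond with
has_proper_part	http://semanticscience.org/resource/SIO_000053	has proper part
is_part_of	http://semanticscience.org/resource/SIO_000068	is part of
has_attribute	http://semanticscience.org/resource/SIO_000008	has attribute
has_value	http://semanticscience.org/resource/SIO_000300	has value
has_unit	http://semanticscience.org/resource/SIO_000221	has unit
has_participant	http://semanticscience.org/resource/SIO_000132	has participant
has_provider	http://semanticscience.org/resource/SIO_hasProvider	has provider
has_direct_part	http://semanticscience.org/resource/SIO_hasDirectPart	has direct part
has_uncertainty	http://semanticscience.org/resource/CHESS_hasUncertainty	has uncertainty
has_coefficient	http://semanticscience.org/resource/CHESS_hasStoichiometricCoefficient	has stoichiometric coefficient
chemical_reaction	http://semanticscience.org/resource/SIO_010345	chemical reaction
has_input	http://semanticscience.org/resource/SIO_000230	has input
has_product	http://semanticscience.org/resource/SIO_000312	has product
has_agent	http://semanticscience.org/resource/SIO_000139	has agent
transforms_into	http://semanticscience.org/resource/SIO_000655	transforms into
chemical_configuration	http://semanticscience.org/resource/SIO_000659	chemical configuration
software_application	http://semanticscience.org/resource/SIO_SoftwareApplication	software application
software_version	http://semanticscience.org/resource/SIO_SoftwareVersion	software version
coordinate_3d	http://semanticscience.org/resource/SIO_3DCartesianCoordinate	3D Cartesian coordinate
coordinate_x	http://semanticscience.org/resource/SIO_xCartesianCoordinate	x Cartesian coordinate
coordinate_y	http://semanticscience.org/resource/SIO_yCartesianCoordinate	y Cartesian coordinate
coordinate_z	http://semanticscience.org/resource/SIO_zCartesianCoordinate	z Cartesian coordinate
bde_descriptor	http://semanticscience.org/resource/CHEMINF_000252	bond dissociation enthalpy descriptor
algorithm	http://semanticscience.org/resource/CHEMINF_000144	algorithm
parameterized_execution	http://semanticscience.org/resource/CHEMINF_000147	parameterized software execution
is_specified_output_of	http://semanticscience.org/resource/CHEMINF_isSpecifiedOutputOf	is specified output of
is_output_of	http://semanticscience.org/resource/CHEMINF_isOutputOf	is output of
mass_descriptor	http://semanticscience.org/resource/CHEMINF_MassDescriptor	mass descriptor
hba_count	http://semanticscience.org/resource/CHEMINF_HydrogenBondAcceptorCount	hydrogen bond acceptor count
hbd_count	http://semanticscience.org/resource/CHEMINF_HydrogenBondDonorCount	hydrogen bond donor count
logp_descriptor	http://semanticscience.org/resource/CHEMINF_LogPDescriptor	logP descriptor
heavy_atom_count	http://semanticscience.org/resource/CHEMINF_HeavyAtomCount	heavy atom count
temperature	http://semanticscience.org/resource/CHESS_Temperature	temperature parameter
unit_kelvin	http://purl.org/obo/owl/UO#UO_0000012	kelvin
unit_angstrom	http://purl.org/obo/owl/UO#UO_0000019	angstrom
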