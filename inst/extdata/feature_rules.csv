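kind,rule_id,enabled,description
A,acceptor_oxygen,TRUE,Any oxygen with formal charge <= 0 (carbonyl; hydroxyl; ether) accepts; direction is the lone-pair axis opposite the mean bond vector
A,acceptor_nitrogen,TRUE,Nitrogen with formal charge <= 0 and a free lone pair: not an aromatic N-H; not an amide N (adjacent carbon double-bonded to O)
D,donor_heavy,TRUE,"N, O or S carrying at least one hydrogen; site on the heavy atom"
P,positive_charged,TRUE,Nitrogen (or other atom) with formal charge > 0
P,positive_basic_amine,TRUE,Neutral sp3 amine nitrogen: single bonds only; not amide; not bonded to an aromatic atom
N,negative_charged,TRUE,Any atom with formal charge < 0
N,negative_carboxyl,TRUE,Neutral carboxylic acid: site at the centroid of the two carboxyl oxygens
H,hydrophobic_group,TRUE,"Connected groups of non-aromatic carbons not bonded to N/O/F, plus Cl/Br/I; site at the group centroid"
R,aromatic_ring,TRUE,5- or 6-membered aromatic ring (explicit aromatic bonds or Kekule alternation); site at centroid with ring normal
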