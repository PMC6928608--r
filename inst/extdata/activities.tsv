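activity	description
ACE inhibitor	Inhibitors of angiotensin-converting enzyme (ACE) (EC 3.4.15.1) (MEROPS ID: M02-001)
activating ubiquitin-mediated proteolysis	Peptides activating proteolysis mediated by ubiquitin
alpha-amylase inhibitor	Inhibitors of alpha-amylase (EC 3.2.1.1)
alpha-glucosidase inhibitor	Inhibitors of alpha-glucosidase (EC 3.2.1.20)
anorectic	Peptides causing a decrease in food intake and suppression of appetite
antiamnestic	Inhibitors of prolyl oligopeptidase (EC 3.4.21.26) (MEROPS ID: S09.001), which degrades neuropeptides involved in memory processes
antibacterial	Peptides revealing any action against bacteria
anticancer	Peptides revealing any action against cancers
antifungal	Peptides revealing any action against fungi
anti-inflammatory	Peptides reducing inflammation or swelling
antioxidative	Peptides inhibiting oxidation
antithrombotic	Inhibitors of blood coagulation, including inhibitors of thrombin (EC 3.4.21.5) (MEROPS ID: S01.217)
antiviral	Peptides revealing any action against viruses, including inhibitors of viral enzymes
bacterial permease ligand	Ligands of bacterial permeases
binding	Peptides binding any biomolecules, including mineral binding peptides
CaMKII inhibitor	Inhibitors of Ca2+/calmodulin-dependent protein kinase (CaMKII) (EC 2.7.11.17)
CaMPDE inhibitor	Inhibitors of 3',5'-cyclic-nucleotide phosphodiesterase (calmodulin-dependent phosphodiesterase 1, CaMPDE) (EC 3.1.4.17)
chemotactic	Peptides inducing chemotaxis, i.e. movement in response to a chemical stimulus
celiac toxic	Peptides toxic to people suffering from celiac disease
contracting	Peptides stimulating muscle contraction
dipeptidyl peptidase III inhibitor	Inhibitors of dipeptidyl peptidase III (EC 3.4.14.4) (MEROPS ID: M49.001)
dipeptidyl peptidase IV inhibitor	Inhibitors of dipeptidyl peptidase IV (EC 3.4.14.5) (MEROPS ID: S09.003)
embryotoxic	Peptides toxic to animal embryos
hemolytic	Peptides destroying red blood cells
heparin binding	Heparin binding peptides
HMG-CoA reductase inhibitor	Inhibitors of 3-hydroxy-3-methyl-glutaryl-coenzyme A reductase (HMG-CoA reductase) (EC 1.1.1.34)
hypotensive	Peptides causing blood pressure decrease
immunomodulating	Peptides modulating activity of the immune system
immunostimulating	Peptides stimulating activity of the immune system
inhibitor	Peptides inhibiting various biological processes
membrane-active	Peptides affecting transmembrane transport
natriuretic	Peptides inducing the excretion of sodium by kidneys (natriuresis)
neuropeptide	Peptides affecting activity of the nervous system
opioid	Ligands of opioid receptors
opioid agonist	Agonists of opioid receptors
opioid antagonist	Antagonists of opioid receptors
orphan receptor GPR14 agonist	Agonists of orphan receptor GPR14
Protein Kinase C inhibitor	Inhibitors of protein kinase C (EC 2.7.11.13)
regulating	Peptides regulating various biological processes
renin inhibitor	Inhibitors of renin (EC 3.4.23.15) (MEROPS ID: A01.007)
stimulating	Peptides stimulating various biological processes
toxic	Toxic peptides
vasoconstrictor	Peptides causing blood pressure increase
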