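gene,sample_id,mutation_type,aa_change,histology,fathmm_prediction,fathmm_score
SF3B1,S001,Substitution - Missense,p.K700E,carcinoma,PATHOGENIC,0.98
SF3B1,S002,Substitution - Missense,p.R625C,carcinoma,PATHOGENIC,0.95
SF3B1,S003,Substitution - Missense,p.K700E,lymphoma,PATHOGENIC,0.97
SF3B1,S004,Substitution - coding silent,p.G83=,carcinoma,NEUTRAL,
DHX15,S005,Substitution - Missense,p.A134V,carcinoma,NEUTRAL,0.40
DHX15,S006,Substitution - Missense,p.R222H,carcinoma,PATHOGENIC,0.85
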