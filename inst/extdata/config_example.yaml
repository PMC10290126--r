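# Example pipeline configuration (all keys optional; defaults shown)
denovo_score_cutoff: 60
peptide_prob_cutoff: 0.95
protein_prob_cutoff: 0.99
pep_max: 0.01
ievalue_max: 1.0e-3
adj_p_cutoff: 0.05
local_fdr_cutoff: 0.05
min_reps_coccolith: 2
min_reps_coccosphere: 3
cluster_similarity_threshold: 0.7
rng_seed: 1
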