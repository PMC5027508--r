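# Termination-product percentages printed in the survey text (mini-gel
# quantification: total TP band density as % of lane density from the well
# to the ~100 nt marker; N = 3 independent repeats). Values reported as
# approximate ("~") in the source text are entered at the stated number.
variant	mean_tp	sd	n_reps	provenance
G5AG7	17	NA	3	in vitro LSP transcription, rCRS substrate, mini-gel densitometry
G7AG6	17	NA	3	in vitro LSP transcription, unoccupied variant, mini-gel densitometry
G3AG9	11	NA	3	in vitro LSP transcription, occupied variant, mini-gel densitometry
G>A	9	NA	3	basal poly-T-driven stalling, G-tract replaced by adenines
G>A_dTP	6	NA	3	non-specific background, G-tract and downstream T-run both removed
dTP	10	NA	3	downstream T291-T283 run deleted, G-tract intact
A6	10	NA	3	downstream T291-T286 run mutated to an A6 run
(UC)3	13	NA	3	alternate downstream thymines mutated to cytosine
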