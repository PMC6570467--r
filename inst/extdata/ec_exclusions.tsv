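prefix	reason
2.7.10	protein-tyrosine kinases
2.7.11	protein-serine/threonine kinases
2.7.12	dual-specificity protein kinases
2.7.13	protein-histidine kinases
3.4	peptidases
2.7.7.6	DNA-directed RNA polymerase
2.7.7.7	DNA-directed DNA polymerase
2.7.7.49	RNA-directed DNA polymerase (reverse transcriptase)
5.6.2	DNA topoisomerases
6.1.1	amino-acid--tRNA ligases
3.1.26	endoribonucleases producing 5'-phosphomonoesters
3.1.27	endoribonucleases producing 3'-phosphomonoesters
3.6.4	ATPases acting on DNA/RNA (nucleic-acid motors)
2.3.2.27	RING-type E3 ubiquitin transferase
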