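# Synthetic CTCF-like motif library (not derived from any published matrix).
# Dialect: one block per motif:
#   >CONSENSUS<TAB>name<TAB>log_odds_threshold_bits<TAB>source
#   pA<TAB>pC<TAB>pG<TAB>pT      (one row per motif position)
# Grammar (EBNF):
#   library  = { block } ;
#   block    = header , { row } ;
#   header   = ">" , consensus , TAB , name , TAB , number , [ TAB , source ] , NL ;
#   row      = number , TAB , number , TAB , number , TAB , number , NL ;
# Probabilities are strictly positive and each row sums to 1 (tol 1e-6).
# Scores are log2(p/0.25) summed over positions; N in a scanned sequence
# contributes 0 bits.
>CCACCAGGGGGCGCT	ctcf_db1	24.954256	database
0.001000	0.997000	0.001000	0.001000
0.001000	0.997000	0.001000	0.001000
0.997000	0.001000	0.001000	0.001000
0.001000	0.997000	0.001000	0.001000
0.001000	0.997000	0.001000	0.001000
0.997000	0.001000	0.001000	0.001000
0.001000	0.001000	0.997000	0.001000
0.001000	0.001000	0.997000	0.001000
0.001000	0.001000	0.997000	0.001000
0.001000	0.001000	0.997000	0.001000
0.001000	0.001000	0.997000	0.001000
0.001000	0.997000	0.001000	0.001000
0.001000	0.001000	0.997000	0.001000
0.001000	0.997000	0.001000	0.001000
0.001000	0.001000	0.001000	0.997000
>CCACTAGGTGGCAGA	ctcf_db2	24.954256	database
0.001000	0.997000	0.001000	0.001000
0.001000	0.997000	0.001000	0.001000
0.997000	0.001000	0.001000	0.001000
0.001000	0.997000	0.001000	0.001000
0.001000	0.001000	0.001000	0.997000
0.997000	0.001000	0.001000	0.001000
0.001000	0.001000	0.997000	0.001000
0.001000	0.001000	0.997000	0.001000
0.001000	0.001000	0.001000	0.997000
0.001000	0.001000	0.997000	0.001000
0.001000	0.001000	0.997000	0.001000
0.001000	0.997000	0.001000	0.001000
0.997000	0.001000	0.001000	0.001000
0.001000	0.001000	0.997000	0.001000
0.997000	0.001000	0.001000	0.001000
>TCCACCAGATGGCGC	ctcf_db3	24.954256	database
0.001000	0.001000	0.001000	0.997000
0.001000	0.997000	0.001000	0.001000
0.001000	0.997000	0.001000	0.001000
0.997000	0.001000	0.001000	0.001000
0.001000	0.997000	0.001000	0.001000
0.001000	0.997000	0.001000	0.001000
0.997000	0.001000	0.001000	0.001000
0.001000	0.001000	0.997000	0.001000
0.997000	0.001000	0.001000	0.001000
0.001000	0.001000	0.001000	0.997000
0.001000	0.001000	0.997000	0.001000
0.001000	0.001000	0.997000	0.001000
0.001000	0.997000	0.001000	0.001000
0.001000	0.001000	0.997000	0.001000
0.001000	0.997000	0.001000	0.001000
>CCGCCAGGGGGAGCT	ctcf_db4	24.954256	database
0.001000	0.997000	0.001000	0.001000
0.001000	0.997000	0.001000	0.001000
0.001000	0.001000	0.997000	0.001000
0.001000	0.997000	0.001000	0.001000
0.001000	0.997000	0.001000	0.001000
0.997000	0.001000	0.001000	0.001000
0.001000	0.001000	0.997000	0.001000
0.001000	0.001000	0.997000	0.001000
0.001000	0.001000	0.997000	0.001000
0.001000	0.001000	0.997000	0.001000
0.001000	0.001000	0.997000	0.001000
0.997000	0.001000	0.001000	0.001000
0.001000	0.001000	0.997000	0.001000
0.001000	0.997000	0.001000	0.001000
0.001000	0.001000	0.001000	0.997000
>ACCACCAGGGGGCAC	ctcf_db5	24.954256	database
0.997000	0.001000	0.001000	0.001000
0.001000	0.997000	0.001000	0.001000
0.001000	0.997000	0.001000	0.001000
0.997000	0.001000	0.001000	0.001000
0.001000	0.997000	0.001000	0.001000
0.001000	0.997000	0.001000	0.001000
0.997000	0.001000	0.001000	0.001000
0.001000	0.001000	0.997000	0.001000
0.001000	0.001000	0.997000	0.001000
0.001000	0.001000	0.997000	0.001000
0.001000	0.001000	0.997000	0.001000
0.001000	0.001000	0.997000	0.001000
0.001000	0.997000	0.001000	0.001000
0.997000	0.001000	0.001000	0.001000
0.001000	0.997000	0.001000	0.001000
>CCACCTGGTGGCAGT	ctcf_disc1	21.186417	discovered
0.050000	0.850000	0.050000	0.050000
0.050000	0.850000	0.050000	0.050000
0.850000	0.050000	0.050000	0.050000
0.050000	0.850000	0.050000	0.050000
0.050000	0.850000	0.050000	0.050000
0.050000	0.050000	0.050000	0.850000
0.050000	0.050000	0.850000	0.050000
0.050000	0.050000	0.850000	0.050000
0.050000	0.050000	0.050000	0.850000
0.050000	0.050000	0.850000	0.050000
0.050000	0.050000	0.850000	0.050000
0.050000	0.850000	0.050000	0.050000
0.850000	0.050000	0.050000	0.050000
0.050000	0.050000	0.850000	0.050000
0.050000	0.050000	0.050000	0.850000
>GCCACCAGGGGGAGCA	ctcf_disc2	22.598845	discovered
0.050000	0.050000	0.850000	0.050000
0.050000	0.850000	0.050000	0.050000
0.050000	0.850000	0.050000	0.050000
0.850000	0.050000	0.050000	0.050000
0.050000	0.850000	0.050000	0.050000
0.050000	0.850000	0.050000	0.050000
0.850000	0.050000	0.050000	0.050000
0.050000	0.050000	0.850000	0.050000
0.050000	0.050000	0.850000	0.050000
0.050000	0.050000	0.850000	0.050000
0.050000	0.050000	0.850000	0.050000
0.050000	0.050000	0.850000	0.050000
0.850000	0.050000	0.050000	0.050000
0.050000	0.050000	0.850000	0.050000
0.050000	0.850000	0.050000	0.050000
0.850000	0.050000	0.050000	0.050000
>CCAGCAGGGGGCACTT	ctcf_disc3	22.598845	discovered
0.050000	0.850000	0.050000	0.050000
0.050000	0.850000	0.050000	0.050000
0.850000	0.050000	0.050000	0.050000
0.050000	0.050000	0.850000	0.050000
0.050000	0.850000	0.050000	0.050000
0.850000	0.050000	0.050000	0.050000
0.050000	0.050000	0.850000	0.050000
0.050000	0.050000	0.850000	0.050000
0.050000	0.050000	0.850000	0.050000
0.050000	0.050000	0.850000	0.050000
0.050000	0.050000	0.850000	0.050000
0.050000	0.850000	0.050000	0.050000
0.850000	0.050000	0.050000	0.050000
0.050000	0.850000	0.050000	0.050000
0.050000	0.050000	0.050000	0.850000
0.050000	0.050000	0.050000	0.850000
>TCCGCCAGCTGGCGCA	ctcf_disc4	22.598845	discovered
0.050000	0.050000	0.050000	0.850000
0.050000	0.850000	0.050000	0.050000
0.050000	0.850000	0.050000	0.050000
0.050000	0.050000	0.850000	0.050000
0.050000	0.850000	0.050000	0.050000
0.050000	0.850000	0.050000	0.050000
0.850000	0.050000	0.050000	0.050000
0.050000	0.050000	0.850000	0.050000
0.050000	0.850000	0.050000	0.050000
0.050000	0.050000	0.050000	0.850000
0.050000	0.050000	0.850000	0.050000
0.050000	0.050000	0.850000	0.050000
0.050000	0.850000	0.050000	0.050000
0.050000	0.050000	0.850000	0.050000
0.050000	0.850000	0.050000	0.050000
0.850000	0.050000	0.050000	0.050000
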