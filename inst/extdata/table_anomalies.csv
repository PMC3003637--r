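table,peptide_sequence,field,printed_value,note
table1_model_peptides,YICENQDTISSKL,log_sum_k1,1.4238,Printed descriptor cannot be reconstructed from any retention-factor assignment consistent with the other rows (reconstruction ~1.435); transcribed verbatim and excluded from the default factor solve.
table1_model_peptides,YICENQDTISSKL,delta_t_r,1.24,Printed value breaks the ascending sort order of the column (neighbours 1.73 and 1.88); transcribed verbatim.
table2_sasp_dprpE,ANNNSGNSNNLLVPGAAQAIDQMK,xcorr,3.41,Listed under the correctly-identified block although 3.41 is below the 3.75 threshold for charge 3; strict thresholds reclassify the row as POTENTIAL_FALSE_NEGATIVE.
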