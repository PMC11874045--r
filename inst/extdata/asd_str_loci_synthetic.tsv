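gene	chrom	start	end
DMPK	chr19	45769709	45770264
FGF14	chr13	102161575	102162131
CACNB1	chr17	39177500	39178060
FXN	chr9	69035752	69037304
CDON	chr11	125951434	125952002
MYOCD	chr17	12665890	12666450
MBOAT7	chr19	54173808	54174370
IL1RAPL1	chrX	28605516	28606074
FMR1	chrX	147912050	147912610
IGF1	chr12	102395874	102396430
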