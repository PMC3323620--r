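>BRAF_ex15 cds_start=1744 hotspots=1795,1797,1799 note=NM_004333_CDS_codons_582-611
ATATTTCTTCATGAAGACCTCACAGTAAAAATAGGTGATTTTGGTCTAGCTACAGTGAAA
TCTCGATGGAGTGGGTCCCATCAGTTTGAA
>BRAF_ex11 cds_start=1384 hotspots=1406 note=abridged_P-loop_segment_codons_462-491
AGAATTGGATCTGGTAGCTTTGGTACAGTGTATAAAGGAAAATGGCATGGAGATGTGGCT
GTTAAAATGCTAAATGTAACAGCTCCTACA
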