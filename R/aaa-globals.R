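# Shared column vocabulary: per-context read support for the four
# assay x tissue contexts (WGS/RNA x normal/polyp), as depth (dp) and
# alt-read (ad) counts.
OBS_COLS <- c("dp_wgs_n", "ad_wgs_n", "dp_wgs_p", "ad_wgs_p",
              "dp_rna_n", "ad_rna_n", "dp_rna_p", "ad_rna_p")
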