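#!/usr/bin/env Rscript

# Step 1: simulate the working cohort.
#
# One chromosome, 60 eRNA-like intervals, 25 donors, with all three
# cohort-scale effects injected: a 50% mutation-density dip over the central
# 400 bp of each interval, boundary peaks, and a downstream pyrimidine-form
# excess (65/35 split). The cohort is written to data/cohort/ in the
# pipeline's on-disk dialects (mutation TSV, BED6, FASTA, flat config) so the
# later steps exercise the same readers a real dataset would.

suppressPackageStartupMessages(library(ernadens))

cfg <- synth_config(seed = 20260101, chrom_length = 3.5e6, n_ernas = 60,
                    n_donors = 25, donor_total_median = 6000,
                    dip_depth = 0.5, dip_halfwidth = 200,
                    peak_height = 1, peak_halfwidth = 150,
                    strand_beta = 0.3)
cohort <- simulate_cohort(cfg, with_reference = TRUE)
write_cohort(cohort, "data/cohort")

message("donors:    ", length(unique(cohort$mutations$donor_id)))
message("mutations: ", nrow(cohort$mutations))
message("intervals: ", nrow(cohort$ernas),
        " covering ", region_size(cohort$ernas), " bp")
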