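# Shared study configuration for the analysis scripts.
# All downstream scripts source this file; everything derives from one seed.

library(metdms)

SEED <- 2026
OUT <- "results/analysis"
dir.create(OUT, showWarnings = FALSE, recursive = TRUE)

# Library: a 60-residue contiguous region in kinase-domain numbering, with
# an early-stop control every 11 residues.
REGION_START <- 1059
REGION_END <- 1118
set.seed(derive_seed(SEED, "wtseq"))
WT_SEQ <- paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                       REGION_END - REGION_START + 1, replace = TRUE),
                collapse = "")

# Conditions: DMSO control, three type I and two type II inhibitors, one
# type I 1/2 -- wild type is dosed at IC50 so it doubles twice per interval
# in every condition.
CONDITIONS <- make_conditions(
  name = c("DMSO", "criz_like", "capm_like", "savo_like",
           "mere_like", "cabo_like", "amg_like"),
  inhibitor_type = c("DMSO", "I_a", "I_a", "I_a", "II", "II", "I_half"))

# Planted resistance sites: solvent-front-like positions for type I,
# back-pocket-like positions for type II, and one site shared with the
# type I 1/2 inhibitor.
pos <- REGION_START:REGION_END
RESISTANCE_SPEC <- list(
  I_a = data.frame(position = pos[c(6, 6, 6, 14, 14, 25)],
                   mut_aa = c("R", "H", "K", "C", "H", "N")),
  II = data.frame(position = pos[c(38, 38, 45, 52)],
                  mut_aa = c("M", "F", "V", "Y")),
  I_half = data.frame(position = pos[c(14, 30)], mut_aa = c("C", "R")))

DESIGN <- sim_design(n_replicates = 3, n_timepoints = 4, depth = 3e5,
                     noise_mode = "multinomial",
                     seed = derive_seed(SEED, "counts"))

say <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...))
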