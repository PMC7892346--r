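# Shared study definition for the analysis scripts. Everything is
# regenerated deterministically from the seed, so each numbered script can
# run standalone; outputs accumulate under results/.

suppressMessages({
  library(splicemut)
  library(data.table)
})

STUDY_SEED <- 20260926L %% 1000003L   # fixed study seed, < 2^31
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

study_config <- function() sim_config(effect_range = c(0.2, 0.6))

study_classes <- function() {
  rep(c("donor_disrupt", "ss_dinucleotide", "acceptor_disrupt", "ppt_disrupt",
        "bp_disrupt", "cryptic_donor_gain", "cryptic_acceptor_gain",
        "cryptic_ppt_gain", "enhancer_gain", "silencer_loss", "neutral"),
      length.out = 55L)
}

build_study <- function() {
  cfg <- study_config()
  genome <- generate_genome(cfg, seed = STUDY_SEED)
  inj <- inject_mutations(genome, study_classes(), seed = STUDY_SEED + 1L)
  cohort <- simulate_cohort(inj$genome, inj$ledger, cfg,
                            seed = STUDY_SEED + 2L)
  list(cfg = cfg, genome = inj$genome, ledger = inj$ledger, cohort = cohort)
}

say <- function(...) message(sprintf(...))
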