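#!/usr/bin/env Rscript
# One-class predictive models for proximal mis-splicing SNVs: train on
# strength-difference features of the mis-splicing set, cross-validate,
# and compare with models trained on randomly selected mutations at the
# same site classes.

source("analysis/00_common.R")

cfg <- study_config()
genome <- generate_genome(cfg, seed = STUDY_SEED)
models <- default_strength_models(genome)

results <- list()
for (mc in c("donor_intronic", "acceptor_intronic")) {
  cl <- if (mc == "donor_intronic") "donor_disrupt" else "acceptor_disrupt"
  inj <- inject_mutations(genome, rep(cl, 60L), seed = STUDY_SEED + 11L)
  pos <- variant_features(inj$genome, inj$ledger[, .(chrom, pos, ref, alt)],
                          models)
  cv_pos <- cross_validate(pos[, .(f1, f2)], folds = 3L, iterations = 200L,
                           nu = 0.05, seed = STUDY_SEED + 12L)
  rnd <- variant_features(genome,
                          random_site_variants(genome, nrow(pos), mc,
                                               seed = STUDY_SEED + 13L),
                          models)
  cv_rnd <- cross_validate(rnd[, .(f1, f2)], folds = 3L, iterations = 200L,
                           nu = 0.05, seed = STUDY_SEED + 12L)
  say("%s: CV accuracy %.1f%% (SD %.1f) vs random-site comparator %.1f%%",
      mc, 100 * cv_pos$mean_accuracy, 100 * cv_pos$sd_by_iteration,
      100 * cv_rnd$mean_accuracy)
  fit <- train_one_class(pos[, .(f1, f2)], nu = 0.05,
                         seed = STUDY_SEED + 14L)
  # label fresh candidates at the same sites
  cand <- variant_features(genome,
                           random_site_variants(genome, 200L, mc,
                                                seed = STUDY_SEED + 15L),
                           models)
  lab <- predict_candidates(fit, cand)
  say("%s: %d/%d fresh random candidates labelled as predicted mis-splicing",
      mc, sum(lab$predicted_missplicing), nrow(lab))
  lab[, model_class := mc]
  results[[mc]] <- lab
}
fwrite(rbindlist(results),
       file.path(RESULTS_DIR, "predicted_candidates.tsv"), sep = "\t")
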