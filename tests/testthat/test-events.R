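# five-exon plus-strand toy for junction geometry: exons of 60 nt starting
# every 150 nt -> introns [60,150), [210,300), [360,450), [510,600)
toy5 <- function() toy_coding()

abn_reads <- function(...) rbindlist(list(...))

test_that("event typing recovers each geometry from junction evidence", {
  t <- toy5()
  kj <- known_junctions(t)
  # annotated donor (60) -> novel intra-intron acceptor: partial retention
  ev <- type_event(abn_reads(ev_row("junction", junctions = "60-100")), t, kj)
  expect_length(ev, 1L)
  expect_equal(ev[[1]]$event_type, "partial_intron_retention")
  expect_equal(ev[[1]]$cryptic_acceptor, 100L)
  expect_equal(ev[[1]]$intron_idx, 1L)
  # novel intra-intron donor -> annotated acceptor
  ev2 <- type_event(abn_reads(ev_row("junction", junctions = "110-150")), t, kj)
  expect_equal(ev2[[1]]$event_type, "partial_intron_retention")
  expect_equal(ev2[[1]]$cryptic_donor, 110L)
  # two novel junctions bracketing an internal interval: pseudoexon
  ev3 <- type_event(abn_reads(
    ev_row("junction", junctions = "60-90;113-150")), t, kj)
  expect_equal(ev3[[1]]$event_type, "pseudoexon_activation")
  expect_equal(pseudoexon_bounds(ev3[[1]])$length, 23L)
  expect_false(ev3[[1]]$one_sided)
  # exon1 donor -> exon3 acceptor skips annotated exon 2
  ev4 <- type_event(abn_reads(ev_row("junction", junctions = "60-300")), t, kj)
  expect_equal(ev4[[1]]$event_type, "full_exon_skipping")
  expect_equal(ev4[[1]]$skipped_exons, 2L)
  # junction truncating exon 2 -> partial exon skipping
  ev5 <- type_event(abn_reads(ev_row("junction", junctions = "60-180")), t, kj)
  expect_equal(ev5[[1]]$event_type, "partial_exon_skipping")
  # retention evidence with no novel junction
  ev6 <- type_event(abn_reads(ev_row("unspliced_span", span = "55-70")), t, kj)
  expect_equal(ev6[[1]]$event_type, "full_intron_retention")
  expect_equal(ev6[[1]]$intron_idx, 1L)
  # two distinct abnormal geometries -> combinatorial wrap-up appended
  ev7 <- type_event(abn_reads(
    ev_row("junction", junctions = "60-100", read_id = "a"),
    ev_row("junction", junctions = "60-300", read_id = "b")), t, kj)
  types <- vapply(ev7, `[[`, "", "event_type")
  expect_true("combinatorial" %in% types)
  expect_setequal(setdiff(types, "combinatorial"),
                  c("partial_intron_retention", "full_exon_skipping"))
})

test_that("event typing is invariant to read order", {
  t <- toy5(); kj <- known_junctions(t)
  rr <- abn_reads(
    ev_row("junction", junctions = "60-90;113-150", read_id = "a"),
    ev_row("junction", junctions = "60-90;113-150", read_id = "b"))
  e1 <- type_event(rr, t, kj)
  e2 <- type_event(rr[2:1], t, kj)
  expect_equal(vapply(e1, `[[`, "", "event_type"),
               vapply(e2, `[[`, "", "event_type"))
  expect_equal(e1[[1]]$abnormal_count, e2[[1]]$abnormal_count)
})

test_that("cryptic dinucleotide audit distinguishes pre-existing GT, GC->GT, and violations", {
  # sequence with GT at position 10 and GC at position 30, AG before 50
  s <- paste0(strrep("A", 10), "GT", strrep("A", 18), "GC",
              strrep("C", 16), "AG", strrep("A", 30))
  ev <- structure(list(event_type = "partial_intron_retention",
                       cryptic_donor = 10L, intron_idx = 1L),
                  class = "splice_event")
  out <- locate_cryptic_sites(ev, s, "+",
                              variant = list(pos = 6L, ref = "A", alt = "T"))
  expect_equal(out$donor_origin, "pre_existing")
  expect_false(out$audit_flag)
  ev2 <- structure(list(event_type = "partial_intron_retention",
                        cryptic_donor = 30L, intron_idx = 1L),
                   class = "splice_event")
  out2 <- locate_cryptic_sites(ev2, s, "+",
                               variant = list(pos = 31L, ref = "C", alt = "T"))
  expect_equal(out2$donor_origin, "created_by_variant")
  out2b <- locate_cryptic_sites(ev2, s, "+",
                                variant = list(pos = 40L, ref = "C", alt = "T"))
  expect_true(out2b$audit_flag)   # GC not converted by this variant
  ev3 <- structure(list(event_type = "partial_intron_retention",
                        cryptic_acceptor = 50L, intron_idx = 1L),
                   class = "splice_event")
  out3 <- locate_cryptic_sites(ev3, s, "+")
  expect_true(out3$acceptor_ag)
  ev4 <- structure(list(event_type = "partial_intron_retention",
                        cryptic_acceptor = 20L, intron_idx = 1L),
                   class = "splice_event")
  expect_true(locate_cryptic_sites(ev4, s, "+")$audit_flag)
})

test_that("pseudoexon bounds report the inclusive interval length", {
  ev <- structure(list(event_type = "pseudoexon_activation",
                       pseudoexon = c(1000L, 1123L)), class = "splice_event")
  expect_equal(pseudoexon_bounds(ev)$length, 123L)
  ev28 <- structure(list(event_type = "pseudoexon_activation",
                         pseudoexon = c(1000L, 1028L)), class = "splice_event")
  expect_equal(pseudoexon_bounds(ev28)$length, 28L)
  bad <- structure(list(event_type = "pseudoexon_activation",
                        pseudoexon = c(1123L, 1000L)), class = "splice_event")
  expect_error(pseudoexon_bounds(bad), "not downstream")
  expect_error(pseudoexon_bounds(structure(list(event_type = "full_exon_skipping"),
                                           class = "splice_event")),
               "not a pseudoexon")
})

test_that("simulator-intended events are typed back to their intended class", {
  st <- small_study()
  led <- st$ledger[!is.na(intended_event)]
  for (j in seq_len(nrow(led))) {
    row <- led[j]
    t <- st$genome$transcripts[[paste0(row$gene_id, ".t1")]]
    kj <- known_junctions(t)
    rd <- st$cohort$reads[sample_id == row$sample_id & gene_id == row$gene_id]
    cl <- classify_reads(rd, t, kj)
    ab <- cl[class == "abnormal"]
    if (!nrow(ab)) next   # low-ratio draws may yield no abnormal reads
    evs <- type_event(ab, t, kj)
    types <- vapply(evs, `[[`, "", "event_type")
    expect_true(row$intended_event %in% types, info = row$class)
  }
})
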