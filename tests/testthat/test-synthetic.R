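test_that("proteome generation is deterministic and records planted motifs", {
  cfg <- synth_config(seed = 101, n_proteins = 8, len_range = c(60, 90))
  g1 <- generate_proteome(cfg)
  g2 <- generate_proteome(cfg)
  expect_identical(g1, g2)

  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(g1$proteome, f1)
  write_fasta(g2$proteome, f2)
  expect_identical(readLines(f1), readLines(f2))

  # the ledger points at verbatim motif instances
  seqs <- setNames(g1$proteome$sequence, g1$proteome$protein_id)
  for (i in seq_len(nrow(g1$ledger))) {
    led <- g1$ledger[i, ]
    expect_equal(substr(seqs[[led$protein_id]], led$start, led$end),
                 led$motif)
  }
  expect_error(synth_config(seed = 1, n_proteins = 0), "at least 1")
  expect_error(generate_proteome(
    synth_config(seed = 1, n_proteins = 2, len_range = c(4, 5))), "longer")
})

test_that("seed is mandatory and probabilities are validated", {
  expect_error(synth_config(), "seed")
  expect_error(synth_config(seed = 1, p_diso = c(tp = 1.2, tn = 0.1)),
               "\\[0, 1\\]")
})

test_that("training sets plant the configured clue frequencies", {
  cfg <- synth_config(seed = 7, n_TP = 4000, n_TN = 4000,
                      p_match = list(prd_motif = c(tp = 0.4, tn = 0.02),
                                     struct = c(tp = 0, tn = 0)))
  ts <- generate_training_sets(cfg)
  expect_equal(ts$pairs$N_TP, 4000)
  tab <- estimate_clue_lr(matches_to_observations(ts$matches), ts$pairs)
  got <- tab$lr[tab$clue_id == "match" & tab$method == "prd_motif"]
  # exact binomial 99% interval around the planted LR of 20
  lo <- (qbinom(0.005, 4000, 0.4) / 4000) / (qbinom(0.995, 4000, 0.02) / 4000)
  hi <- (qbinom(0.995, 4000, 0.4) / 4000) / (qbinom(0.005, 4000, 0.02) / 4000)
  expect_gt(got, lo)
  expect_lt(got, hi)
})

test_that("equal clue frequencies give LR near 1", {
  cfg <- synth_config(seed = 8, n_TP = 4000, n_TN = 4000,
                      p_match = list(prd_motif = c(tp = 0.3, tn = 0.3),
                                     struct = c(tp = 0, tn = 0)))
  ts <- generate_training_sets(cfg)
  tab <- estimate_clue_lr(matches_to_observations(ts$matches), ts$pairs)
  got <- tab$lr[tab$clue_id == "match" & tab$method == "prd_motif"]
  lo <- (qbinom(0.005, 4000, 0.3) / 4000) / (qbinom(0.995, 4000, 0.3) / 4000)
  hi <- (qbinom(0.995, 4000, 0.3) / 4000) / (qbinom(0.005, 4000, 0.3) / 4000)
  expect_gt(got, lo)
  expect_lt(got, hi)
})

test_that("training sets never overlap TP and TN and are reproducible", {
  cfg <- synth_config(seed = 9, n_TP = 300, n_TN = 500)
  t1 <- generate_training_sets(cfg)
  t2 <- generate_training_sets(cfg)
  expect_identical(t1, t2)
  expect_equal(t1$pairs$N_TP, 300)
  expect_equal(t1$pairs$N_TN, 500)
})

test_that("toy complexes place the peptide at the requested gap", {
  tc4 <- generate_toy_complex(14, "PPLPARK", gap = 4.0)
  expect_gt(length(interfacial_residues(tc4$template)), 0)
  tc6 <- generate_toy_complex(14, "PPLPARK", gap = 6.0)
  expect_length(interfacial_residues(tc6$template), 0)

  # the realized minimum atom-atom distance equals the gap
  at <- tc4$structure$atoms
  a <- at[at$chain == "A", ]; b <- at[at$chain == "B", ]
  d2 <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 +
    outer(a$z, b$z, "-")^2
  expect_equal(sqrt(min(d2)), 4.0, tolerance = 1e-6)

  expect_error(generate_toy_complex(14, "PPLP", gap = 4), "\\[5, 35\\]")
  expect_error(generate_toy_complex(
    14, paste(rep("A", 36), collapse = ""), gap = 4), "\\[5, 35\\]")
})

test_that("planted motifs are disordered and conserved, background is not", {
  cfg <- synth_config(seed = 15, n_proteins = 20, len_range = c(150, 200))
  gp <- generate_proteome(cfg)
  tr <- generate_tracks_and_msa(gp$proteome, gp$ledger, cfg)

  # disorder: planted motifs flag with prob >= 0.95, background <= 0.05
  n_flag <- 0
  for (i in seq_len(nrow(gp$ledger))) {
    led <- gp$ledger[i, ]
    d <- motif_disorder(tr$disorder[[led$protein_id]], led$start, led$end)
    n_flag <- n_flag + d$disordered
  }
  expect_gte(n_flag / nrow(gp$ledger), 0.95)

  withr::with_seed(16, {
    bg_flags <- replicate(200, {
      id <- sample(gp$proteome$protein_id, 1)
      L <- gp$proteome$length[gp$proteome$protein_id == id]
      led <- gp$ledger[gp$ledger$protein_id == id, ]
      s <- sample(L - 8, 1)
      # resample windows overlapping a planted motif
      while (nrow(led) > 0 && any(s <= led$end & s + 7 >= led$start)) {
        s <- sample(L - 8, 1)
      }
      motif_disorder(tr$disorder[[id]], s, s + 7)$disordered
    })
    expect_lte(mean(bg_flags), 0.05)
  })

  # conservation: every planted motif residue is locally conserved
  n_consv <- 0
  for (i in seq_len(nrow(gp$ledger))) {
    led <- gp$ledger[i, ]
    sc <- column_conservation(tr$msas[[led$protein_id]], led$protein_id)
    fl <- local_conservation(sc)
    n_consv <- n_consv + motif_conserved(fl, led$start, led$end)
  }
  expect_gte(n_consv / nrow(gp$ledger), 0.9)

  # determinism
  tr2 <- generate_tracks_and_msa(gp$proteome, gp$ledger, cfg)
  expect_identical(tr$disorder, tr2$disorder)
  expect_identical(tr$msas, tr2$msas)
})

test_that("combined DMI and NS evidence amplifies strong predictions", {
  for (seed in c(2, 5, 11)) {
    cfg <- synth_config(seed = seed, n_TP = 800, n_TN = 800)
    ts <- generate_training_sets(cfg)
    fit <- dmi_nb(ts$matches, ts$pairs)
    all_pairs <- rbind(ts$pairs$positives, ts$pairs$negatives)
    dmi_only <- predict(fit, ts$matches, ns_table = NULL,
                        extra_pairs = all_pairs)
    combined <- predict(fit, ts$matches, ns_table = ts$ns,
                        extra_pairs = all_pairs)
    ns_only <- flag_strong(ns_lookup(ts$ns, all_pairs$protein_a,
                                     all_pairs$protein_b))
    expect_gte(sum(combined$strong), sum(dmi_only$strong))
    expect_gte(sum(combined$strong), sum(ns_only))
  }
})
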