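# Small hand-built training fixture: 10 TP, 100 TN pairs, one binary clue
# carried by 4 TP and 2 TN pairs.
fixture_pairs <- function() {
  tp <- data.frame(protein_a = sprintf("T%02d", 1:10),
                   protein_b = sprintf("U%02d", 1:10))
  tn <- data.frame(protein_a = sprintf("N%03d", 1:100),
                   protein_b = sprintf("M%03d", 1:100))
  pair_set(tp, tn)
}

fixture_obs <- function() {
  data.frame(
    protein_a = c(sprintf("T%02d", 1:4), sprintf("N%03d", 1:2)),
    protein_b = c(sprintf("U%02d", 1:4), sprintf("M%03d", 1:2)),
    method = "prd_motif", clue_id = "match", value = "present",
    stringsAsFactors = FALSE)
}

test_that("clue LR estimation implements the counting formula", {
  tab <- estimate_clue_lr(fixture_obs(), fixture_pairs())
  expect_equal(tab$n_TP, 4)
  expect_equal(tab$n_TN, 2)
  expect_equal(tab$lr, (4 / 10) / (2 / 100))   # = 20
  expect_false(tab$capped)
})

test_that("zero cells give LR 0 (never in TP) or the cap (never in TN)", {
  obs <- fixture_obs()
  obs_tn_only <- obs[5:6, ]
  tab0 <- estimate_clue_lr(obs_tn_only, fixture_pairs())
  expect_equal(tab0$lr, 0)

  obs_tp_only <- obs[1:4, ]
  tabc <- estimate_clue_lr(obs_tp_only, fixture_pairs())
  expect_equal(tabc$lr, 1e6)
  expect_true(tabc$capped)

  empty <- pair_set(data.frame(protein_a = "A", protein_b = "B"),
                    data.frame(protein_a = "C", protein_b = "D"))
  expect_error(estimate_clue_lr(
    data.frame(protein_a = "Z", protein_b = "W", method = "m",
               clue_id = "c", value = "v"), empty), "outside")
})

test_that("additive smoothing shrinks extreme LRs", {
  obs <- fixture_obs()[1:4, ]                 # clue only ever seen in TP
  tab <- estimate_clue_lr(obs, fixture_pairs(), alpha = 1)
  # K = 1 observed value: LR = ((4+1)/(10+1)) / ((0+1)/(100+1))
  expect_equal(tab$lr, (5 / 11) / (1 / 101))
  expect_false(tab$capped)
})

test_that("clue LR estimation matches brute-force counting", {
  withr::with_seed(41, {
    for (rep in 1:8) {
      cfg <- synth_config(seed = sample.int(1e6, 1),
                          n_TP = sample(30:120, 1),
                          n_TN = sample(30:120, 1))
      ts <- generate_training_sets(cfg)
      obs <- matches_to_observations(ts$matches)
      tab <- estimate_clue_lr(obs, ts$pairs)
      ora <- oracle_clue_lr(obs, ts$pairs)
      got <- data.frame(group = paste(tab$method, tab$clue_id, tab$value),
                        n_TP = tab$n_TP, n_TN = tab$n_TN, lr = tab$lr,
                        stringsAsFactors = FALSE)
      got <- got[order(got$group), ]
      rownames(got) <- rownames(ora) <- NULL
      expect_equal(got, ora)
    }
  })
})

test_that("the PRD/motif combination formula follows the normalization", {
  expect_equal(dmi_lr_prd_motif(2, 8, 4, 3), 24)   # 2*4*2*1.5
  m <- 7.3
  expect_equal(dmi_lr_prd_motif(m, m, m, m), m)    # identity
  expect_equal(dmi_lr_prd_motif(m, m, m, m * 3), m * 3)
  expect_error(dmi_lr_prd_motif(0, 1, 1, 1), "untrained")
})

test_that("the Struct combination formula follows the normalization", {
  expect_equal(dmi_lr_struct(2, 6, 10, 4, 2), 60)  # 2*3*5*2*1
  m <- 2.5
  expect_equal(dmi_lr_struct(m, m, m, m, m), m)
  expect_equal(dmi_lr_struct(2, 6, 20, 4, 2), 120) # linear in each factor
  expect_error(dmi_lr_struct(0, 1, 1, 1, 1), "untrained")
})

test_that("both formulas equal their algebraic reductions", {
  withr::with_seed(43, {
    x <- matrix(exp(runif(5 * 200, -4, 4)), ncol = 5)
    got_p <- dmi_lr_prd_motif(x[, 1], x[, 2], x[, 3], x[, 4])
    red_p <- x[, 2] * x[, 3] * x[, 4] / x[, 1]^2
    expect_equal(got_p, red_p, tolerance = 1e-12)
    got_s <- dmi_lr_struct(x[, 1], x[, 2], x[, 3], x[, 4], x[, 5])
    red_s <- x[, 2] * x[, 3] * x[, 4] * x[, 5] / x[, 1]^3
    expect_equal(got_s, red_s, tolerance = 1e-12)
  })
})

test_that("per-pair aggregation takes the maximum by default", {
  expect_equal(aggregate_pair(c(50, 200)), 200)
  expect_equal(aggregate_pair(7), 7)
  expect_equal(aggregate_pair(numeric(0)), 1)       # no DMI evidence
  expect_equal(aggregate_pair(c(50, 200), policy = "product"), 10000)
  # adding a match never lowers the pair LR under max
  withr::with_seed(44, {
    for (i in 1:10) {
      v <- exp(runif(sample(1:6, 1), -2, 6))
      expect_gte(aggregate_pair(c(v, exp(runif(1, -2, 6)))),
                 aggregate_pair(v))
    }
  })
})

test_that("NS combination and the PrePPI merge rule multiply correctly", {
  expect_equal(combine_with_ns(24, 30), 720)
  expect_equal(combine_with_ns(24, 1), 24)
  expect_error(combine_with_ns(0, 5), "positive")

  expect_equal(merge_preppi(100, 40, 2), 200)
  expect_equal(merge_preppi(40, 100, 2), 200)
  expect_equal(merge_preppi(0, 0, 5), 0)
  expect_error(merge_preppi(1, 1, 0), "positive")
})

test_that("posterior probability calibrates to the prior odds", {
  expect_identical(posterior(600, 1 / 600), 0.5)
  expect_equal(posterior(0), 0)
  expect_equal(posterior(600, 1 / 1200), 1 / 3)
  # strictly increasing in LR, approaching 1
  lr <- c(0, 1, 10, 600, 1e4, 1e6, 1e9)
  p <- posterior(lr)
  expect_true(all(diff(p) > 0))
  expect_gt(posterior(1e6), 0.999)
  expect_equal(lr_for_posterior(0.5), 600)
})

test_that("strong predictions use a strict threshold", {
  expect_false(flag_strong(600))
  expect_true(flag_strong(600.01))
  expect_false(flag_strong(0))
  expect_error(flag_strong(-1), "non-negative")
})

test_that("the fitted classifier scores, aggregates and flags pairs", {
  withr::with_seed(45, {
    cfg <- synth_config(seed = 99, n_TP = 400, n_TN = 400)
    ts <- generate_training_sets(cfg)
    fit <- dmi_nb(ts$matches, ts$pairs)
    expect_s3_class(fit, "dmi_nb")
    expect_output(print(fit), "naive Bayes", ignore.case = TRUE)
    expect_true(all(coef(fit) >= 0))

    pred <- predict(fit, ts$matches, ns_table = ts$ns,
                    extra_pairs = rbind(ts$pairs$positives,
                                        ts$pairs$negatives))
    expect_equal(nrow(pred), 800)
    expect_identical(pred$strong, pred$lr_final > 600)
    expect_equal(pred$lr_final, pred$lr_dmi * pred$lr_ns)
    # pairs with no match carry the neutral DMI LR
    mkey <- unique(paste(pmin(ts$matches$protein_a, ts$matches$protein_b),
                         pmax(ts$matches$protein_a, ts$matches$protein_b)))
    pkey <- paste(pred$protein_a, pred$protein_b)
    expect_true(all(pred$lr_dmi[!pkey %in% mkey] == 1))

    # per-match scores agree with the closed-form reductions
    sc <- score_matches(fit, ts$matches)
    expect_length(sc, nrow(ts$matches))
    expect_true(all(sc >= 0))
  })
})

test_that("unseen clue values score as uninformative at prediction time", {
  fit <- dmi_nb(data.frame(
    protein_a = c("T01", "N001"), protein_b = c("U01", "M001"),
    method = "prd_motif", source = "C1", class = "C1",
    psd = NA_character_, sim = NA_character_, diso = TRUE, consv = TRUE,
    stringsAsFactors = FALSE), fixture_pairs())
  new_match <- data.frame(protein_a = "Q1", protein_b = "Q2",
                          method = "prd_motif", source = "C9", class = "C9",
                          psd = NA_character_, sim = NA_character_,
                          diso = TRUE, consv = TRUE,
                          stringsAsFactors = FALSE)
  lr_match <- (1 / 10) / (1 / 100)
  lr_flag <- lr_match   # diso/consv TRUE observed on the same pairs
  expect_equal(score_matches(fit, new_match),
               dmi_lr_prd_motif(lr_match, 1, lr_flag, lr_flag))
})
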