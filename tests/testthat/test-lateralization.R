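# Expressed-transcript gating and the paired L/R lateralization filter.

# small matrix builder: ratios[p, e] = per-embryo R/L fold for probe p
em_from_ratios <- function(ratios, base = 1000, calls = NULL) {
  n_emb <- ncol(ratios)
  probes <- if (is.null(rownames(ratios)))
    paste0("p", seq_len(nrow(ratios))) else rownames(ratios)
  samples <- as.vector(t(outer(paste0("E", seq_len(n_emb)), c("L", "R"),
                               paste, sep = "_")))
  expr <- matrix(0, nrow(ratios), 2 * n_emb,
                 dimnames = list(probes, samples))
  for (e in seq_len(n_emb)) {
    expr[, 2 * e - 1] <- base
    expr[, 2 * e] <- base * ratios[, e]
  }
  if (is.null(calls))
    calls <- matrix("P", nrow(expr), ncol(expr), dimnames = dimnames(expr))
  meta <- data.frame(sample = samples,
                     embryo = rep(paste0("E", seq_len(n_emb)), each = 2),
                     side = rep(c("L", "R"), n_emb))
  expression_matrix(expr, calls, meta)
}

test_that("expressed filter needs a present call per embryo and intensity >= floor", {
  em <- em_from_ratios(matrix(1, 3, 3,
                              dimnames = list(c("hi", "absent2", "low"),
                                              NULL)))
  em$expr["low", ] <- 150
  em$calls["absent2", c("E2_L", "E2_R")] <- "A"
  kept <- filter_expressed(em)
  expect_identical(kept, "hi")
  # present in one sample of each embryo is enough
  em$calls["hi", c("E1_L", "E2_R", "E3_L")] <- "A"
  expect_identical(filter_expressed(em), "hi")
  # floor is inclusive
  em$expr["low", "E1_R"] <- 200
  expect_setequal(filter_expressed(em), c("hi", "low"))
})

test_that("lateralization rule: same sign, mean and 2 embryos over the fold", {
  r <- rbind(sym = c(1, 1, 1),
             right_ok = c(1.7, 1.8, 1.3),
             right_weak = c(1.7, 1.8, 1 / 1.05),   # sign flips
             right_onehot = c(4, 1.2, 1.2),        # only 1 embryo > 1.5
             left_ok = 1 / c(1.7, 1.8, 1.3))
  gs <- detect_lateralized(em_from_ratios(r))
  expect_identical(gs$right_enriched, "right_ok")
  expect_identical(gs$left_enriched, "left_ok")
  # hand-computed mean log2 for the detected probe
  expect_equal(gs$mean_log2_ratio[["right_ok"]],
               mean(log2(c(1.7, 1.8, 1.3))))
  # printed to four truncated decimals as 0.5849
  expect_identical(floor(gs$thresholds$log2_fold * 1e4) / 1e4, 0.5849)
})

test_that("a probe exactly at the fold threshold is not called (strict >)", {
  r <- rbind(at_thr = c(1.5, 1.5, 1.5))
  gs <- detect_lateralized(em_from_ratios(r))
  expect_length(gs$right_enriched, 0)
  # a zero per-embryo ratio breaks the same-sign requirement
  r2 <- rbind(tied = c(2, 2, 1))
  expect_length(detect_lateralized(em_from_ratios(r2))$right_enriched, 0)
})

test_that("side-label swap swaps the enriched lists exactly", {
  ds <- make_expression_dataset(n_probes = 500, n_left_enriched = 12,
                                n_right_enriched = 17, fold = 2,
                                noise_sigma_log2 = 0.1, seed = 11)
  em <- ds$matrix
  gs <- detect_lateralized(em)
  em_sw <- em
  em_sw$meta$side <- ifelse(em$meta$side == "L", "R", "L")
  gs_sw <- detect_lateralized(em_sw)
  expect_setequal(gs_sw$left_enriched, gs$right_enriched)
  expect_setequal(gs_sw$right_enriched, gs$left_enriched)
})

test_that("detection is invariant to probe and sample order", {
  ds <- make_expression_dataset(n_probes = 300, n_left_enriched = 8,
                                n_right_enriched = 9, fold = 2,
                                noise_sigma_log2 = 0.15, seed = 12)
  em <- ds$matrix
  gs <- detect_lateralized(em)
  set.seed(13)
  pi_ <- sample(nrow(em$expr)); si <- sample(ncol(em$expr))
  em2 <- expression_matrix(em$expr[pi_, si], em$calls[pi_, si],
                           em$meta[match(colnames(em$expr)[si],
                                         em$meta$sample), ])
  gs2 <- detect_lateralized(em2)
  expect_setequal(gs2$left_enriched, gs$left_enriched)
  expect_setequal(gs2$right_enriched, gs$right_enriched)
})

test_that("filter and detection agree with the per-probe loop oracle", {
  for (seed in 1:5) {
    ds <- make_expression_dataset(n_probes = 100, n_left_enriched = 5,
                                  n_right_enriched = 5, fold = 1.8,
                                  noise_sigma_log2 = 0.3, seed = seed)
    em <- ds$matrix
    orc <- oracle_lateralized(em)
    gs <- detect_lateralized(em)
    expect_setequal(gs$left_enriched, orc$left)
    expect_setequal(gs$right_enriched, orc$right)
  }
})

test_that("category proportions sum to 100 per side", {
  gs <- structure(list(left_enriched = paste0("p", 1:4),
                       right_enriched = "p9"),
                  class = "lateralized_gene_set")
  ann <- data.frame(probe = paste0("p", c(1, 2, 3, 9)),
                    category = c("nucleus", "nucleus", "nucleus",
                                 "membrane"))
  cp <- category_proportions(gs, ann)
  left <- cp[cp$side == "left", ]
  expect_setequal(left$category, c("nucleus", "unannotated"))
  expect_equal(left$percent[left$category == "nucleus"], 75)
  expect_equal(sum(left$percent), 100)
  expect_equal(cp$percent[cp$side == "right"], 100)
})

test_that("qPCR relative expression is 2^-dCt with per-embryo R/L ratios", {
  ct <- data.frame(embryo = rep(c("E1", "E2"), each = 2),
                   side = rep(c("L", "R"), 2),
                   ct_target = c(20, 20, 25.3, 24.1),
                   ct_reference = c(18, 18, 20, 20))
  q <- qpcr_relative(ct)
  expect_equal(q$ratios$ratio[q$ratios$embryo == "E1"], 1)
  expect_equal(q$ratios$ratio[q$ratios$embryo == "E2"], 2^1.2,
               tolerance = 1e-9)
  ct$ct_reference[2] <- NA
  expect_error(qpcr_relative(ct), class = "MissingReference")
})
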