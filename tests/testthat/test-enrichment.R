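test_that("rpkm applies per-kilobase per-million scaling with validation", {
  expect_equal(rpkm(10, 1e6, 1000), 10)
  expect_equal(rpkm(0, 1e6, 1000), 0)
  expect_equal(rpkm(20, 2e6, 1000), rpkm(10, 1e6, 1000))  # joint scaling cancels
  expect_equal(rpkm(10, 1e6, 500), 2 * rpkm(10, 1e6, 1000))  # 1/length
  expect_error(rpkm(10, 0, 1000), class = "lassocapture_invalid_counts")
  expect_error(rpkm(10, 1e6, 0), class = "lassocapture_invalid_counts")
  expect_error(rpkm(-1, 1e6, 10), class = "lassocapture_invalid_counts")
})

make_table <- function(t_rpkm, o_rpkm, probe = "A") {
  # invert rpkm to raw reads at a fixed library size and length 1000
  lib <- 1e9
  tibble::tibble(
    sequence_id = paste0("s", seq_len(length(t_rpkm) + length(o_rpkm))),
    length_nt = 1000,
    reads = c(t_rpkm, o_rpkm),
    is_target = rep(c(TRUE, FALSE), c(length(t_rpkm), length(o_rpkm))),
    probe_id = probe,
    rpkm = c(t_rpkm, o_rpkm)
  )
}

test_that("enrichment ratio is the ratio of stratum medians", {
  expect_equal(enrichment_ratio(make_table(c(2, 4, 6), c(1, 1, 1))), 4)
  expect_equal(enrichment_ratio(make_table(c(3, 3), c(3, 3, 3))), 1)
  # even-sized stratum: mean of the central pair
  expect_equal(enrichment_ratio(make_table(c(1, 2, 3, 10), c(1, 1))), 2.5)
  tbl <- make_table(c(2, 4, 6), c(1, 5, 3))
  expect_equal(enrichment_ratio(tbl[sample.int(6), ]), enrichment_ratio(tbl))
  expect_error(enrichment_ratio(make_table(c(1, 2), numeric(0))),
               class = "lassocapture_invalid_table")
  expect_error(enrichment_ratio(make_table(c(1, 2), c(0, 0, 0))),
               class = "lassocapture_zero_offtarget")
})

test_that("free-energy transforms of RPKM obey the log identities", {
  expect_equal(dg_from_rpkm(3, 3), 0)
  expect_equal(dg_from_rpkm(exp(1) * 5, 5), -1)
  a <- 7.3; b <- 0.41; cc <- 12.9
  expect_equal(dg_from_rpkm(a, b), -dg_from_rpkm(b, a))
  expect_equal(dg_from_rpkm(a, b) + dg_from_rpkm(b, cc), dg_from_rpkm(a, cc))
  expect_error(dg_from_rpkm(0, 1), class = "lassocapture_invalid_rpkm")

  rel <- relative_dg(c(A = 10, B = 10))
  expect_equal(rel$dg_rel, c(0, 0))           # ties at the maximum both map to 0
  rel2 <- relative_dg(c(A = 10, B = 10 / exp(1)))
  expect_equal(rel2$dg_rel, c(0, 1))
  set.seed(2)
  v <- setNames(runif(6, 0.1, 9), letters[1:6])
  expect_equal(min(relative_dg(v)$dg_rel), 0)
  expect_true(all(relative_dg(v)$dg_rel >= 0))
  expect_equal(relative_dg(v * 17.3)$dg_rel, relative_dg(v)$dg_rel)  # scale-free
  expect_error(relative_dg(c(A = 1)), class = "lassocapture_invalid_table")
})

test_that("pearson_r matches hand-computed product-moment values", {
  expect_equal(pearson_r(1:5, 2 * (1:5) + 1), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(1:3, 1:4), class = "lassocapture_invalid_argument")
  expect_error(pearson_r(1:2, 1:2), class = "lassocapture_invalid_argument")
  expect_error(pearson_r(c(1, 1, 1), 1:3), class = "lassocapture_zero_variance")
})

test_that("per-probe summaries assemble RPKM, enrichment and relative dG", {
  cfg <- synth_config(seed = 8, adapter_lens = c(10L, 30L, 60L),
                      propensities = c(1, 2, 0.5), true_enrichment = 20)
  tbl <- gen_read_table(cfg)
  # compare probes on a common sequencing-depth scale: per-probe library
  # normalization would partially absorb the capture propensity itself
  tbl <- add_rpkm(tbl, reads_lib = 1e6)
  summ <- enrich_summary(tbl)
  expect_equal(nrow(summ), 3L)
  expect_equal(min(summ$dg_rel), 0)
  expect_equal(summ$probe_id[summ$dg_rel == 0], "AL30")  # highest propensity wins
  # recovered dG differences reflect the generating propensity log-ratios
  dg_ab <- summ$dg_rel[summ$probe_id == "AL10"] - summ$dg_rel[summ$probe_id == "AL30"]
  expect_equal(dg_ab, log(2), tolerance = 0.35)
  g <- glance(summ)
  expect_equal(g$best_probe, "AL30")
})

test_that("relative dG recovers generating propensities within count noise", {
  props <- c(1, 0.5, 0.25)
  reps <- lapply(1:12, function(s) {
    cfg <- synth_config(seed = 400 + s, adapter_lens = c(10L, 30L, 60L),
                        propensities = props, mean_depth = 200)
    enrich_summary(add_rpkm(gen_read_table(cfg), reads_lib = 1e6))$dg_rel
  })
  m <- do.call(rbind, reps)
  est <- colMeans(m)
  se <- apply(m, 2, sd) / sqrt(nrow(m))
  truth <- -log(props / max(props))
  expect_true(all(abs(est - truth) < 3 * pmax(se, 0.02)))
})
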