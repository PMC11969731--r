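test_that("simulate_transcriptome is deterministic and spans length classes", {
  a <- simulate_transcriptome(3, lengths = c(100, 5000, 50000), seed = 1)
  expect_equal(as.character(trichotomize(a)), c("short", "medium", "long"))

  b1 <- simulate_transcriptome(50, seed = 7)
  b2 <- simulate_transcriptome(50, seed = 7)
  expect_identical(b1, b2)

  expect_error(simulate_transcriptome(0), class = "nascentflow_config_error")
  expect_error(simulate_transcriptome(5, length_sdlog = -1),
               class = "nascentflow_config_error")
})

test_that("n_uridines tracks read length, not gene length", {
  a <- simulate_transcriptome(4, lengths = c(100, 1e6), read_length = 100,
                              u_fraction = 0.3, seed = 2)
  expect_true(all(a$n_uridines == 30L))
  b <- simulate_transcriptome(4, lengths = c(100, 1e6), read_length = 50,
                              u_fraction = 0.3, seed = 2)
  expect_true(all(b$n_uridines == 15L))
})

test_that("lognormal length-class proportions match the closed-form CDF mass", {
  ml <- log(3000); sl <- 1.2
  a <- simulate_transcriptome(1000, length_meanlog = ml, length_sdlog = sl,
                              seed = 2)
  cls <- table(trichotomize(a))
  expected <- c(short = plnorm(250, ml, sl),
                medium = plnorm(10001, ml, sl) - plnorm(250, ml, sl),
                long = 1 - plnorm(10001, ml, sl))
  for (k in names(expected)) {
    se <- sqrt(expected[[k]] * (1 - expected[[k]]) / 1000)
    expect_lt(abs(cls[[k]] / 1000 - expected[[k]]), 4 * se + 1e-3)
  }
})

test_that("intron intervals are non-overlapping and inside the gene span", {
  a <- simulate_transcriptome(200, seed = 5)
  for (i in seq_len(nrow(a))) {
    iv <- a$introns[[i]]
    if (!nrow(iv)) next
    expect_true(all(iv$start < iv$end))
    expect_true(all(iv$start >= 0) && all(iv$end <= a$length_nt[i]))
    if (nrow(iv) > 1) expect_true(all(diff(iv$start) > 0) &&
                                    all(iv$end[-nrow(iv)] <= iv$start[-1]))
  }
})

test_that("labeling_model validates its rates", {
  expect_error(labeling_model(10, 0.2, labeled_fraction = 1.5),
               class = "nascentflow_config_error")
  expect_error(labeling_model(10, 0.11),  # 10 * 0.11 >= 1
               class = "nascentflow_config_error")
  expect_error(labeling_model(-1, 1e-4), class = "nascentflow_config_error")
  m <- labeling_model(10, 1e-4, 1e-4, 0.5, seed = 3)
  expect_s3_class(m, "labeling_model")
})

test_that("simulate_slam_counts matches binomial-tail expectations", {
  ann <- tiny_annotation()
  # no conversion source at all
  m0 <- labeling_model(10, 1e-4, background_error_rate = 0,
                       labeled_fraction = 0, seed = 1)
  c0 <- simulate_slam_counts(ann, m0, 1000)
  expect_true(all(c0$tcReadCount == 0))
  expect_true(all(c0$readCount == 1000))

  # saturated regime: P(>=1 conversion) > 0.999 per read
  msat <- labeling_model(30, 0.01, background_error_rate = 0,
                         labeled_fraction = 1, seed = 1)
  expect_gt(tc_tail(30, 30 * 0.01), 0.999)
  cs <- simulate_slam_counts(ann, msat, 10000)
  expect_true(all(cs$tcReadCount / cs$readCount > 0.99))

  # determinism
  m <- labeling_model(10, 1e-4, 1e-4, 0.5, seed = 11)
  expect_identical(simulate_slam_counts(ann, m, 5000),
                   simulate_slam_counts(ann, m, 5000))
})

test_that("interactome simulation honors the spike design", {
  expect_error(interactome_design(10, n_replicates = 1),
               class = "nascentflow_config_error")
  expect_error(interactome_design(10, spiked = c(ZZZ = 1)),
               class = "nascentflow_config_error")

  # null design with vanishing noise: all post-normalization log2FC ~ 0
  d0 <- interactome_design(20, lognormal_sigma = 1e-9, seed = 4)
  tab <- differential_interactome(
    bait_normalize(pseudo_floor(simulate_interactome(d0))),
    "control", "treated")
  expect_true(all(abs(tab$log2FC) < 1e-6))

  # a -2 spike is recovered as lost by the downstream module
  d1 <- interactome_design(50, lognormal_sigma = 0.1,
                           spiked = c(P0001 = -2), seed = 4)
  tab1 <- differential_interactome(
    bait_normalize(pseudo_floor(simulate_interactome(d1))),
    "control", "treated")
  expect_identical(tab1$class[tab1$protein_id == "P0001"], "lost")

  # determinism
  expect_identical(simulate_interactome(d1)$intensity,
                   simulate_interactome(d1)$intensity)

  # missing detections are exact zeros, never on the bait
  d2 <- interactome_design(100, missing_rate = 0.2, seed = 9)
  m2 <- simulate_interactome(d2)
  expect_gt(sum(m2$intensity == 0), 0)
  expect_true(all(m2$intensity["BAIT", ] > 0))
})

test_that("IPA coverage simulation produces the stated step", {
  ann <- simulate_transcriptome(30, lengths = 3000, exon_lambda = 3, seed = 6)
  flat <- simulate_ipa_coverage(ann, 0, depth = 100, seed = 1)
  expect_true(all(vapply(flat, function(p) is.na(p$true_ipa_site), TRUE)))
  expect_lt(abs(mean(flat[[1]]$depth) - 100), 3 * sqrt(100 / length(flat[[1]]$depth)))

  half <- simulate_ipa_coverage(ann, 0.5, depth = 100, seed = 1)
  p <- half[[1]]
  k <- p$true_ipa_site - p$intron["start"]
  down <- p$depth[(k + 1):length(p$depth)]
  expect_lt(abs(mean(down) - 50), 3 * sqrt(50 / length(down)))

  full <- simulate_ipa_coverage(ann, 1, depth = 100, seed = 1)
  p <- full[[1]]
  k <- p$true_ipa_site - p$intron["start"]
  expect_equal(mean(p$depth[(k + 1):length(p$depth)]), 0)
})

test_that("substream splitting is deterministic and component-specific", {
  expect_identical(substream_seed(42, "slam"), substream_seed(42, "slam"))
  expect_false(substream_seed(42, "slam") == substream_seed(42, "ipa"))
  expect_false(substream_seed(42, "slam") == substream_seed(43, "slam"))
  s <- substream_seed(.Machine$integer.max, "x")
  expect_true(s >= 0 && s < 2^31)
})
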