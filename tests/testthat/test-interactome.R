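toy_matrix <- function(intensity, conditions = c("control", "treated"),
                       bait = "BAIT") {
  ns <- ncol(intensity)
  stopifnot(ns %% 2 == 0)
  samples <- data.frame(
    sample_id = colnames(intensity),
    condition = rep(conditions, each = ns / 2),
    replicate = rep(seq_len(ns / 2), 2),
    stringsAsFactors = FALSE)
  structure(list(intensity = intensity, samples = samples, bait_id = bait),
            class = "IntensityMatrix")
}

test_that("pseudo_floor codes zeros to 1, leaves the rest, and is idempotent", {
  m <- matrix(c(0, 57.3, 2, 0), 2, dimnames = list(c("BAIT", "P1"), c("s1", "s2")))
  f <- pseudo_floor(m)
  expect_equal(unname(f["BAIT", ]), c(1, 2))
  expect_equal(unname(f["P1", ]), c(57.3, 1))
  expect_equal(unclass(pseudo_floor(f)), unclass(f))
  expect_error(pseudo_floor(matrix(-1)), class = "nascentflow_format_error")
})

test_that("bait_normalize fixes the bait row at 1 and is column-scale invariant", {
  m <- matrix(c(400, 200, 800, 100), 2,
              dimnames = list(c("BAIT", "P1"), c("s1", "s2")))
  nm <- bait_normalize(m, "BAIT")
  expect_equal(unname(nm["BAIT", ]), c(1, 1))
  expect_equal(unname(nm["P1", ]), c(0.5, 0.125))

  set.seed(3)
  scale <- runif(2, 0.1, 10)
  expect_equal(bait_normalize(sweep(m, 2, scale, "*"), "BAIT"), nm)

  expect_error(bait_normalize(m, "NOPE"), class = "nascentflow_format_error")
  m0 <- m; m0["BAIT", 1] <- 0
  expect_error(bait_normalize(m0, "BAIT"),
               class = "nascentflow_format_error")
})

test_that("differential_interactome reproduces the worked example", {
  intensity <- rbind(
    BAIT = rep(1, 6),
    P1 = c(0.10, 0.11, 0.09, 0.40, 0.44, 0.36))
  colnames(intensity) <- sprintf("s%d", 1:6)
  tab <- differential_interactome(toy_matrix(intensity), "control", "treated")
  p1 <- tab[tab$protein_id == "P1", ]
  expect_equal(p1$fold_change, 4)
  expect_equal(p1$log2FC, 2)
  # t-test oracle computed directly
  oracle_p <- t.test(c(0.40, 0.44, 0.36), c(0.10, 0.11, 0.09),
                     var.equal = TRUE)$p.value
  expect_equal(p1$p_value, oracle_p)
  expect_equal(p1$class, "gained")
  expect_equal(tab$class[tab$protein_id == "BAIT"], "unchanged")

  # identical replicate sets: fold change 1, unchanged
  flat <- rbind(BAIT = rep(1, 6), P2 = rep(0.3, 6))
  colnames(flat) <- sprintf("s%d", 1:6)
  tf <- differential_interactome(toy_matrix(flat), "control", "treated")
  expect_equal(tf$fold_change[tf$protein_id == "P2"], 1)
  expect_equal(tf$class[tf$protein_id == "P2"], "unchanged")
})

test_that("the floor -> normalize order is enforced", {
  d <- interactome_design(20, seed = 2, missing_rate = 0.1)
  raw <- simulate_interactome(d)
  expect_error(differential_interactome(raw, "control", "treated"),
               class = "nascentflow_format_error")
  # swapping the order gives different numbers: floor-after-normalize turns
  # missing detections into 1.0 "normalized" values, floor-first does not
  good <- bait_normalize(pseudo_floor(raw))$intensity
  swapped <- pseudo_floor(bait_normalize(raw))$intensity
  expect_false(isTRUE(all.equal(unclass(good), unclass(swapped),
                                check.attributes = FALSE)))
  tab <- differential_interactome(bait_normalize(pseudo_floor(raw)),
                                  "control", "treated")
  expect_true(any(tab$imputed_floor))
})

test_that("per-sample scaling cancels after bait normalization", {
  d <- interactome_design(40, lognormal_sigma = 0.3, seed = 6)
  mat <- pseudo_floor(simulate_interactome(d))
  tab1 <- differential_interactome(bait_normalize(mat), "control", "treated")
  set.seed(9)
  mat2 <- mat
  mat2$intensity <- sweep(mat2$intensity, 2, runif(ncol(mat2$intensity), 0.2, 5), "*")
  tab2 <- differential_interactome(bait_normalize(mat2), "control", "treated")
  expect_equal(tab1$fold_change, tab2$fold_change, tolerance = 1e-12)
  expect_equal(tab1$p_value, tab2$p_value, tolerance = 1e-9)
})

test_that("classes are recomputable from p-value and log2FC alone", {
  d <- interactome_design(100, lognormal_sigma = 0.4, seed = 13,
                          spiked = c(P0001 = 3, P0002 = -3))
  tab <- differential_interactome(
    bait_normalize(pseudo_floor(simulate_interactome(d))),
    "control", "treated")
  recls <- ifelse(tab$p_value < 0.05 & tab$log2FC > 0, "gained",
                  ifelse(tab$p_value < 0.05 & tab$log2FC < 0, "lost",
                         "unchanged"))
  expect_identical(tab$class, recls)
})

test_that("dual_response_filter applies the stringent double cut", {
  mk <- function(ids, lfc, p) data.frame(protein_id = ids, log2FC = lfc,
                                         p_value = p, stringsAsFactors = FALSE)
  ids <- c("A", "B", "C", "D")
  ta <- mk(ids, c(2.5, 2.5, 0.5, -2.5), c(0.01, 0.01, 0.01, 0.2))
  tb <- mk(ids, c(2.2, -2.2, 2.5, -2.5), c(0.03, 0.01, 0.01, 0.01))
  got <- dual_response_filter(ta, tb, lfc_cutoff = 2)
  expect_setequal(got$protein_id, c("A", "B"))
  expect_equal(got$concordance[got$protein_id == "A"], "concordant-gained")
  expect_equal(got$concordance[got$protein_id == "B"], "discordant")

  none <- dual_response_filter(mk("A", 0, 1), mk("A", 0, 1))
  expect_equal(nrow(none), 0)
  expect_error(dual_response_filter(ta, mk("Z", 1, 1)),
               class = "nascentflow_config_error")
})

test_that("selective_sets enumerates exclusive sets and patterns", {
  mk <- function(lost) data.frame(
    protein_id = c("p1", "p2", "p3"),
    log2FC = ifelse(c("p1", "p2", "p3") %in% lost, -2, 0),
    p_value = ifelse(c("p1", "p2", "p3") %in% lost, 0.01, 0.9),
    class = ifelse(c("p1", "p2", "p3") %in% lost, "lost", "unchanged"),
    stringsAsFactors = FALSE)
  res <- selective_sets(list(A = mk(c("p1", "p2")), B = mk("p2"), C = mk(character(0))))
  expect_equal(res$lost$exclusive$A, "p1")
  expect_equal(res$lost$exclusive$B, character(0))
  expect_equal(res$lost$exclusive$C, character(0))
  expect_equal(res$lost$patterns$size[res$lost$patterns$pattern == "A&B"], 1L)
  expect_equal(nrow(res$gained$patterns), 0)

  # universe-wide significance in all conditions: exclusive sets all empty
  all_lost <- mk(c("p1", "p2", "p3"))
  res2 <- selective_sets(list(A = all_lost, B = all_lost))
  expect_true(all(lengths(res2$lost$exclusive) == 0))
})

test_that("complex_summary reports per-member relative binding", {
  # bait alone: relative binding exactly 1
  flat <- rbind(BAIT = rep(1, 6))
  colnames(flat) <- sprintf("s%d", 1:6)
  res <- complex_summary(toy_matrix(flat), "BAIT", "control", "treated")
  expect_equal(res$per_member$relative_binding, 1)

  # 15 members at a uniform 25% reduction, low noise
  set.seed(14)
  members <- sprintf("INT%02d", 1:15)
  ctrl <- matrix(rlnorm(15 * 3, log(0.2), 0.02), 15)
  trt <- ctrl * 0.75 * matrix(rlnorm(15 * 3, 0, 0.02), 15)
  m <- rbind(rep(1, 6), cbind(ctrl, trt))
  rownames(m) <- c("BAIT", members); colnames(m) <- sprintf("s%d", 1:6)
  res2 <- complex_summary(toy_matrix(m), c(members, "GHOST"),
                          "control", "treated")
  expect_equal(res2$complex_mean, 0.75, tolerance = 0.05)
  expect_true(all(res2$per_member$relative_binding < 1))
  expect_equal(res2$frac_below_1, 1)
  expect_equal(res2$missing, "GHOST")

  expect_error(complex_summary(toy_matrix(flat), "GHOST", "control", "treated"),
               class = "nascentflow_format_error")
})
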