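itc_panel_assay <- function() {
  ## WT Kd 128 nM; a triple mutant at 427 nM; singles at 194, 187 and an
  ## unchanged 129 nM -- the canonical fold-change arithmetic of an ITC panel
  assay_table(
    variant = c("WT", "Var3", "A:H310A", "A:N315K", "A:H435K"),
    mutations = c("", "A:H310A;A:N315K;A:H435K",
                  "A:H310A", "A:N315K", "A:H435K"),
    kd_nm = c(128, 427, 194, 187, 129))
}

test_that("fold-change calls reproduce the worked assay arithmetic", {
  calls <- call_positions(itc_panel_assay(), threshold = 1.5)
  get <- function(p, col) calls[calls$position == p, col]
  expect_equal(get("A:310", "fold_change"), 194 / 128)
  expect_equal(get("A:310", "status"), "disrupted")      # 1.52-fold
  expect_equal(get("A:435", "fold_change"), 129 / 128)
  expect_equal(get("A:435", "status"), "neutral")
  ## the triple mutant yields a variant-level call only
  vc <- attr(calls, "variant_calls")
  expect_equal(vc$fold_change[vc$variant == "Var3"], 427 / 128)
  expect_equal(vc$status[vc$variant == "Var3"], "disrupted")   # ~3.3-fold
  expect_false("A:H310A;A:N315K;A:H435K" %in% calls$position)
  ## an unchanged Kd is neutral
  same <- assay_table(c("WT", "A:A5K"), c("", "A:A5K"), c(100, 100))
  expect_equal(call_positions(same)$status, "neutral")
})

test_that("the disruption threshold and slack band behave as documented", {
  a <- assay_table(c("WT", "A:A1K", "A:A2K", "A:A3K"),
                   c("", "A:A1K", "A:A2K", "A:A3K"),
                   c(100, 150, 149, 130))
  calls <- call_positions(a, threshold = 1.5)
  expect_equal(calls$status[calls$position == "A:1"], "disrupted")  # at threshold
  expect_equal(calls$status[calls$position == "A:2"], "neutral")
  ## with slack, the band between threshold/slack and threshold is untested
  calls2 <- call_positions(a, threshold = 1.5, neutral_slack = 1.25)
  expect_equal(calls2$status[calls2$position == "A:3"], "untested")
  expect_equal(calls2$status[calls2$position == "A:2"], "untested")
  expect_error(assay_table(c("A:A1K"), c("A:A1K"), 100), "WT")
})

test_that("model filtering matches direct predicate evaluation", {
  epis <- list(M1 = c("T:1", "T:2"), M2 = c("T:2", "T:5"), M3 = c("T:1", "T:5"))
  calls <- data.frame(position = c("T:1", "T:2", "T:5"),
                      status = c("disrupted", "disrupted", "neutral"))
  expect_identical(filter_models(epis, calls), "M1")
  ## no calls -> all models pass
  expect_identical(filter_models(epis, calls[0, ]), c("M1", "M2", "M3"))
  ## contradictory calls on one position -> empty set
  contra <- data.frame(position = c("T:1", "T:1"),
                       status = c("disrupted", "neutral"))
  expect_length(filter_models(epis, contra), 0L)
})

test_that("filtering equals the exhaustive oracle on random instances", {
  set.seed(14)
  for (rep in 1:50) {
    homodimer <- rep %% 2L == 0L
    chains <- if (homodimer) c("A", "B") else "A"
    sym <- if (homodimer) symmetry_map(list(c("A", "B"))) else symmetry_map()
    sym_groups <- if (homodimer) list(c("A", "B")) else list()
    pos_all <- as.vector(outer(chains, 1:6, paste, sep = ":"))
    n_models <- sample(2:6, 1)
    epis <- setNames(lapply(seq_len(n_models), function(i)
      sort(sample(pos_all, sample(0:4, 1)))), paste0("M", seq_len(n_models)))
    ncall <- sample(1:4, 1)
    calls <- data.frame(
      position = paste0("A:", sample(1:6, ncall)),
      status = sample(c("disrupted", "neutral"), ncall, replace = TRUE),
      stringsAsFactors = FALSE)
    expect_identical(filter_models(epis, calls, sym),
                     oracle_filter(epis, calls, sym_groups))
  }
})

test_that("homodimer symmetry lets a single-protomer epitope satisfy calls", {
  hd <- make_homodimer_complex()     # binder touches chain A only
  epi <- epitope_of_model(hd$structure, hd$partition)
  ## calls phrased on chain B (the mutation exists on both protomers)
  calls <- data.frame(position = paste0("B:", 3:4),
                      status = rep("disrupted", 2))
  expect_identical(filter_models(list(M1 = epi), calls, hd$sym), "M1")
  expect_length(filter_models(list(M1 = epi), calls, symmetry_map()), 0L)
})

test_that("the builtin interface score has the analytic LJ minimum and symmetries", {
  part <- chain_partition("R", "T")
  mk <- function(d) pdb_structure(data.frame(
    chain = c("R", "T"), resno = 1L, insert = "", resid = "ALA",
    elety = "CB", elesy = "C", x = c(0, d), y = 0, z = 0, o = 1))
  sigma_c <- 3.40; eps_c <- 0.086
  ## two neutral carbons at the LJ minimum: pair energy -eps
  e <- score_interface(mk(2^(1/6) * sigma_c), part)
  expect_equal(e$value, -eps_c, tolerance = 1e-12)
  expect_false(e$clash)
  ## chains far apart: zero
  expect_equal(score_interface(mk(50), part)$value, 0)
  ## partition swap leaves the score unchanged
  s <- toy_a()
  expect_equal(score_interface(s, chain_partition("R", "T"))$value,
               score_interface(s, chain_partition("T", "R"))$value)
  ## rigid transform of the whole complex leaves the score unchanged
  s_rt <- transform_structure(s, rot_z(33), c(7, -2, 1))
  expect_equal(score_interface(s_rt, chain_partition("R", "T"))$value,
               score_interface(s, chain_partition("R", "T"))$value,
               tolerance = 1e-6)
  ## steric overlap raises the clash flag
  expect_true(score_interface(mk(0.3), part)$clash)
})

test_that("oppositely charged side-chain termini attract in the Coulomb term", {
  mk2 <- function(res_t, atom_t) pdb_structure(data.frame(
    chain = c("R", "T"), resno = 1L, insert = "",
    resid = c("LYS", res_t), elety = c("NZ", atom_t),
    elesy = c("N", "O"), x = c(0, 4), y = 0, z = 0, o = 1))
  e_attr <- score_interface(mk2("GLU", "OE1"), chain_partition("R", "T"))$value
  e_neut <- score_interface(mk2("SER", "OG"), chain_partition("R", "T"))$value
  expect_lt(e_attr, e_neut)
})

test_that("imported energy tables drive table-mode scoring", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("model_id\tenergy", "D01\t-812.5", "D02\t-790.1"), f)
  tab <- read_energy_table(f)
  s <- toy_a(); s$id <- "D02"
  e <- score_interface(s, toy_part(), scorer = "table", table = tab)
  expect_equal(e$value, -790.1)
  expect_equal(e$source, "imported")
  s$id <- "D99"
  expect_error(score_interface(s, toy_part(), scorer = "table", table = tab),
               "absent")
})

test_that("ranking sorts ascending, breaks ties lexicographically and respects the filter", {
  rk <- rank_and_select(c(M1 = -5, M2 = -9, M3 = -1), filtered = c("M1", "M3"))
  expect_identical(rk$ranking$model_id, c("M1", "M3"))
  expect_identical(rk$selected, "M1")    # global minimum M2 is excluded
  ## singleton
  expect_identical(rank_and_select(c(A = 1), "A")$selected, "A")
  ## ties break by id
  expect_identical(rank_and_select(c(B = 2, A = 2))$ranking$model_id,
                   c("A", "B"))
  ## empty filtered set is an explicit no-consistent-model outcome
  empty <- rank_and_select(c(M1 = -5), filtered = character(0))
  expect_true(empty$no_consistent)
  expect_true(is.na(empty$selected))
  expect_error(rank_and_select(c(M1 = 1), filtered = "M9"), "missing")
})

test_that("spearman_rho matches the mid-rank oracle and flags constants", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30)), 1.0)
  expect_equal(spearman_rho(1:3, c(3, 2, 1)), -1.0)
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  expect_equal(spearman_rho(x, y), oracle_spearman(x, y), tolerance = 1e-12)
  set.seed(2)
  for (rep in 1:5) {
    x <- sample(1:5, 8, replace = TRUE); y <- sample(1:5, 8, replace = TRUE)
    if (length(unique(x)) == 1L || length(unique(y)) == 1L) next
    expect_equal(spearman_rho(x, y), oracle_spearman(x, y), tolerance = 1e-12)
  }
  expect_warning(r <- spearman_rho(c(1, 1, 1), 1:3), "constant")
  expect_true(is.na(r))
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("filtering improves planted-native recovery under a noisy scorer", {
  r <- planted_native_recovery(n_trials = 40, seed = 3)
  expect_gte(r$with_filter, r$without_filter)
  expect_true(r$native_id %in% r$consistent)
})
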