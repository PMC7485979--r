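three_species_aln <- function() {
  homolog_alignment(
    c(human = "KHQHEA", mouse = "KHQQDA", rabbit = "KQEHAA"),
    reference = "human", ref_keys = paste0("T:", 1:6))
}

test_that("conservation classes follow the distinct-residue count", {
  aln <- three_species_aln()
  cls <- classify_conservation(aln, paste0("T:", 1:6))
  expect_equal(cls$class,
               c("shared_by_all",   # K/K/K
                 "shared_by_two",   # H/H/Q
                 "shared_by_two",   # Q/Q/E
                 "shared_by_two",   # H/Q/H
                 "unique",          # E/D/A
                 "shared_by_all"))  # A/A/A
  expect_error(classify_conservation(aln, "T:99"), "not mapped")
})

test_that("conservation classification is invariant to species order", {
  seqs <- c(human = "KHQHEA", mouse = "KHQQDA", rabbit = "KQEHAA")
  base <- classify_conservation(
    homolog_alignment(seqs, "human", paste0("T:", 1:6)), paste0("T:", 1:6))
  perm <- classify_conservation(
    homolog_alignment(seqs[c(3, 1, 2)], "human", paste0("T:", 1:6)),
    paste0("T:", 1:6))
  expect_identical(base$class, perm$class)
})

test_that("gaps count as distinct residues and the column map is validated", {
  aln <- homolog_alignment(c(a = "KA-T", b = "KAST", c = "KA-T"),
                           reference = "b", ref_keys = paste0("T:", 1:4))
  cls <- classify_conservation(aln, "T:3")
  expect_equal(cls$class, "shared_by_two")   # S vs gap/gap
  expect_error(homolog_alignment(c(a = "KAT", b = "KA"), "a", paste0("T:", 1:3)),
               "differ in length")
  expect_error(homolog_alignment(c(a = "KAT"), "a", paste0("T:", 1:2)),
               "ungapped length")
})

test_that("homolog alignments read from FASTA", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">human", "KHQHEA", ">mouse", "KHQQDA", ">rabbit", "KQEHAA"), f)
  aln <- read_homolog_alignment(f, ref_keys = paste0("T:", 1:6))
  expect_equal(aln$reference, "human")
  expect_equal(unname(aln$colmap["T:5"]), 5L)
})

test_that("specificity candidates rank binder residues by divergent contacts", {
  ## binder residues 1-3 contact divergent positions T:2,T:3,T:5; residue 5
  ## contacts conserved T:6 only
  s <- make_toy_complex(toy_spec(5, 6, contacts = rbind(
    c(1, 2), c(2, 3), c(3, 5), c(5, 6))))
  cls <- classify_conservation(three_species_aln(), paste0("T:", 1:6))
  ranked <- specificity_candidates(s, toy_part(), cls)
  expect_equal(ranked$divergent_contacts[ranked$binder_res == "R:5"], 0L)
  expect_true(all(ranked$binder_res[ranked$divergent_contacts > 0] %in%
                    c("R:1", "R:2", "R:3")))
  expect_true(!is.unsorted(rev(ranked$divergent_contacts)))
  ## empty interface -> empty ranking
  far <- transform_structure(s, translation = c(0, 50, 0), chains = "R")
  expect_equal(nrow(specificity_candidates(far, toy_part(), cls)), 0L)
})

test_that("mutation scans are complete, deterministic and exclude Cys/Pro", {
  s <- make_toy_complex(toy_spec(3, 6, contacts = cbind(1, 2),
                                 target_seq = "ADDDAA"))
  tg <- list(hFc = list(structure = s, partition = toy_part()))
  m <- scan_mutations(c("R:1", "R:2"), tg)
  ## |positions| x (20 - |exclude| - 1) x |targets| rows, wt excluded
  expect_equal(nrow(m), 2 * (20 - 2 - 1) * 1)
  expect_false(any(m$sub %in% c("C", "P")))
  expect_false(any(m$sub == m$wt))
  expect_identical(m, scan_mutations(c("R:1", "R:2"), tg))
  ## wild type scores zero by convention when included
  m_wt <- scan_mutations("R:1", tg, include_wt = TRUE)
  expect_equal(m_wt$score[m_wt$sub == m_wt$wt], 0)
  expect_error(scan_mutations("R:99", tg), "absent")
  expect_error(scan_mutations("T:2", tg), "binder chain")
})

test_that("a planted charge-complementary substitution scores lowest", {
  ## binder residue 1 faces an aspartate: basic substitutions gain the most
  s <- make_toy_complex(toy_spec(3, 6, contacts = cbind(1, 2),
                                 target_seq = "ADDDAA"))
  tg <- list(hFc = list(structure = s, partition = toy_part()))
  m <- scan_mutations("R:1", tg)
  best <- m$sub[m$score == min(m$score)]
  expect_true("K" %in% best)
  expect_true(all(best %in% c("H", "K", "R")))
  expect_lt(min(m$score), 0)
  ## a non-contacting position is indifferent to substitution
  m2 <- scan_mutations("R:3", tg)
  expect_true(all(m2$score == 0))
})

test_that("per-target ddG tables drive the scan verbatim", {
  s <- make_toy_complex(toy_spec(2, 4, contacts = cbind(1, 2)))
  tg <- list(hFc = list(structure = s, partition = toy_part()),
             mFc = list(structure = s, partition = toy_part()))
  subs <- setdiff(c("A","C","D","E","F","G","H","I","K","L","M","N","P",
                    "Q","R","S","T","V","W","Y"), "A")
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chain\tnumber\ticode\twt\tsub\tddg",
               sprintf("R\t1\t\tA\t%s\t%g", subs,
                       seq(-1, by = 0.1, length.out = 19))), f1)
  writeLines(c("chain\tnumber\ticode\twt\tsub\tddg",
               sprintf("R\t1\t\tA\t%s\t%g", subs,
                       seq(2, by = 0.1, length.out = 19))), f2)
  tabs <- list(hFc = read_ddg_table(f1), mFc = read_ddg_table(f2))
  m <- scan_mutations("R:1", list(hFc = tg$hFc, mFc = tg$mFc), tables = tabs)
  expect_equal(m$score[m$target == "hFc" & m$sub == "D"], -0.9)
  expect_equal(m$score[m$target == "mFc" & m$sub == "D"], 2.1)
})

test_that("greedy two-position design picks stagewise aggregate minima", {
  mk_row <- function(pos, sub, target, score)
    data.frame(position = pos, wt = "S", sub = sub, target = target,
               score = score, stringsAsFactors = FALSE)
  ## stage 1 favors M at pos1 for both targets; given M, stage 2 favors R
  mat <- rbind(
    mk_row("R:241", "M", "hFc", -2), mk_row("R:241", "M", "mFc", -3),
    mk_row("R:241", "L", "hFc", -2.5), mk_row("R:241", "L", "mFc", 1),
    mk_row("R:244", "R", "hFc", -1), mk_row("R:244", "R", "mFc", -2),
    mk_row("R:244", "E", "hFc", 0.5), mk_row("R:244", "E", "mFc", -4))
  rec <- greedy_double_design(mat, "R:241", "R:244", aggregate = "worst_case")
  expect_equal(format(rec$mutations[[1]]), "R:S241M")
  expect_equal(format(rec$mutations[[2]]), "R:S244R")
  expect_equal(rec$stage_scores$stage2[["mFc"]], -2)
  ## single target: the aggregate is irrelevant, equals the argmin
  single <- mat[mat$target == "hFc", ]
  rec1 <- greedy_double_design(single, "R:241", "R:244", aggregate = "sum")
  expect_equal(rec1$mutations[[1]]$sub, "L")
  expect_error(greedy_double_design(mat[0, ], "R:241", "R:244"), "no candidate")
})

test_that("greedy design with additive scores equals the exhaustive pair optimum", {
  set.seed(19)
  subs <- c("D", "E", "K", "M", "R")
  for (rep in 1:5) {
    rows <- list()
    for (pos in c("R:1", "R:2")) for (sb in subs) for (tg in c("t1", "t2"))
      rows[[length(rows) + 1L]] <- data.frame(
        position = pos, wt = "A", sub = sb, target = tg,
        score = round(rnorm(1), 3), stringsAsFactors = FALSE)
    mat <- do.call(rbind, rows)
    rec <- greedy_double_design(mat, "R:1", "R:2", aggregate = "sum")
    got <- sum(rec$stage_scores$stage1) + sum(rec$stage_scores$stage2)
    ## exhaustive enumeration over all substitution pairs (no interaction)
    best <- Inf
    for (s1 in subs) for (s2 in subs) {
      v <- sum(mat$score[mat$position == "R:1" & mat$sub == s1]) +
        sum(mat$score[mat$position == "R:2" & mat$sub == s2])
      best <- min(best, v)
    }
    expect_equal(got, best, tolerance = 1e-9)
  }
})

test_that("a rescan callback lets stage 2 see the mutated background", {
  mk <- function(pos, sub, sc) data.frame(position = pos, wt = "A", sub = sub,
                                          target = "t", score = sc,
                                          stringsAsFactors = FALSE)
  mat <- rbind(mk("R:1", "K", -1), mk("R:1", "E", 0),
               mk("R:2", "K", -5), mk("R:2", "E", -1))
  rescan <- function(sub1) {
    ## in the K background, K at pos2 is penalized (like-charge clash)
    if (sub1 == "K") rbind(mk("R:2", "K", 3), mk("R:2", "E", -2))
    else mat[mat$position == "R:2", ]
  }
  rec <- greedy_double_design(mat, "R:1", "R:2", rescan = rescan)
  expect_equal(rec$mutations[[2]]$sub, "E")
})

test_that("loop replacements are recorded verbatim at sequence level", {
  rec <- loop_replacement("R:239", "RNSAGSVA", "GG")
  expect_equal(rec$segment$removed, "RNSAGSVA")
  expect_equal(rec$segment$inserted, "GG")
  expect_equal(rec$segment$start, "R:239")
  expect_error(loop_replacement("bogus", "AA", "G"), "malformed")
})
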