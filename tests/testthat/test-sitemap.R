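test_that("variant names parse into residues and sites", {
  expect_equal(parse_variant("L69D/L71D"), c(69L, 71L))
  expect_equal(parse_variant("WT"), integer(0))
  expect_error(parse_variant("L69"), "cannot parse")
  expect_equal(variant_site("R46A/R47A"), "basic")
  expect_equal(variant_site("W44D/L69D/L71D"), "hydrophobic")
  expect_equal(variant_site("R122D/K123D"), "site2")
  expect_equal(variant_site("D87N"), "ad_risk")
  expect_true(is.na(variant_site("WT")))
})

test_that("panel building joins folds, sites and classes", {
  panel <- build_panel(read_panel())
  wt <- panel[panel$variant == "WT" & panel$ligand == "apoE4", ]
  expect_equal(wt$fold_2dp, 1)
  expect_equal(wt$direction, "none")
  l69 <- panel[panel$variant == "L69D" & panel$ligand == "apoE4", ]
  expect_equal(l69$fold_2dp, 195.94)
  nbd <- panel[panel$variant == "L69D/L71D" & panel$ligand == "apoE4", ]
  expect_equal(nbd$class, "no_binding_detected")
  expect_true(is.na(nbd$fold))
  # qualitative (class-only) panels get NA folds but keep classes
  tdp <- panel[panel$ligand == "TDP-43", ]
  expect_true(all(is.na(tdp$fold)))
  expect_equal(sum(tdp$class == "no_binding_detected"), 3)
  # missing WT reference is an error
  expect_error(build_panel(read_panel()[-1, ]), "missing WT")
})

test_that("fold-change columns reproduce the tabulated values or are flagged", {
  chk <- check_fold_table(build_panel(read_panel()))
  expect_true(all(chk$match | chk$note == "one_unit_rounding_mismatch" |
                  chk$variant == "R122D/K123D"))
  # the one-final-digit rounding case is surfaced, not hidden
  w44 <- chk[chk$variant == "W44D" & chk$ligand == "apoE4", ]
  expect_equal(w44$note, "one_unit_rounding_mismatch")
  expect_equal(w44$fold_computed, 9.13)
})

test_that("site calls aggregate verdicts deterministically", {
  panel <- build_panel(read_panel())
  apo <- call_sites(panel, "apoE4")
  expect_equal(apo$primary, "hydrophobic")
  v <- apo$verdicts
  expect_equal(v$verdict[v$site == "hydrophobic"], "ablating")
  expect_equal(v$verdict[v$site == "basic"], "moderate")
  expect_true(v$has_enhancing[v$site == "site2"])

  il34 <- call_sites(panel, "IL-34")
  expect_equal(il34$primary, "basic")
  expect_equal(il34$verdicts$verdict[il34$verdicts$site == "hydrophobic"],
               "neutral")

  # identical inputs, identical calls
  expect_identical(call_sites(panel, "C1q"), call_sites(panel, "C1q"))

  # all-neutral synthetic panel: no primary site
  syn <- data.frame(variant = c("WT", "L69D", "R46D"),
                    ligand = "syn", KD = c(100, 100, 100), KD_unit = "nM",
                    fold_printed = "", class = "binding")
  syn$KD_M <- syn$KD * 1e-9
  calls <- call_sites(build_panel(syn), "syn")
  expect_true(is.na(calls$primary))
  expect_true(all(calls$verdicts$verdict == "neutral"))
  expect_error(call_sites(panel, "nope"), "no variant records")
})

test_that("raising the severe threshold never upgrades a verdict", {
  panel <- build_panel(read_panel())
  rank_of <- c(neutral = 0, enhancing = 1, moderate = 2, severe = 3,
               ablating = 4)
  for (lig in c("apoE4", "IL-34", "C1q")) {
    prev <- NULL
    for (thr in c(5, 10, 20, 50)) {
      v <- call_sites(panel, lig, severe_fold = thr)$verdicts
      r <- rank_of[v$verdict[order(v$site)]]
      if (!is.null(prev)) expect_true(all(r <= prev))
      prev <- r
    }
  }
})

test_that("the ligand-site matrix summarises all calls with stable ordering", {
  panel <- build_panel(read_panel())
  calls <- lapply(c("apoE4", "TDP-43", "C1q", "IL-34"),
                  function(l) call_sites(panel, l))
  m <- ligand_site_matrix(calls)
  expect_equal(nrow(m), 4)
  expect_equal(m$primary[m$ligand == "apoE4"], "hydrophobic")
  expect_equal(m$primary[m$ligand == "TDP-43"], "hydrophobic")
  expect_equal(m$primary[m$ligand == "C1q"], "basic")
  expect_equal(m$primary[m$ligand == "IL-34"], "basic")
  # single ligand -> one-row matrix; identical calls -> identical rows
  one <- ligand_site_matrix(calls[[1]])
  expect_equal(nrow(one), 1)
  two <- ligand_site_matrix(list(calls[[1]], calls[[1]]))
  expect_equal(two[1, -1], two[2, -1], ignore_attr = TRUE)
})

test_that("region annotations and config round-trip", {
  r <- region_annotations()
  expect_true(all(c("CDR1", "CDR2", "CDR3") %in% r$name))
  expect_equal(r$start[r$name == "ig_domain"], 18)
  path <- withr::local_tempfile(fileext = ".json")
  write_region_config(r, path)
  expect_equal(read_region_config(path), r, ignore_attr = TRUE)
})

test_that("FASTA I/O round-trips sequences", {
  seqs <- c(recA = "MKWVTFISLLLF", recB = "IRIRIRIR")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, path)
  expect_equal(read_fasta(path), seqs)
  # bundled synthetic fixture screens to a passing hit at its plant site (45)
  fx <- read_fasta(system.file("extdata", "synthetic_screen_pair.fasta",
                               package = "bliscan"))
  hits <- screen(unname(fx["synthetic_ligand_helix"]),
                 unname(fx["synthetic_receptor_ig_domain"]))
  at <- hits[hits$orientation == "forward" & hits$window_start == 45, ]
  expect_true(at$passes)
  expect_equal(at$percent_match, 100)
})

test_that("the command-line interface runs the sitemap subcommand", {
  cli <- system.file("cli", "bliscan", package = "bliscan")
  out <- withr::local_tempfile(fileext = ".tsv")
  status <- system2("Rscript", c(cli, "sitemap", "--out", out,
                                 "--log-level", "quiet"),
                    stdout = NULL, stderr = NULL)
  expect_equal(status, 0)
  m <- utils::read.delim(out)
  expect_equal(m$primary[m$ligand == "IL-34"], "basic")
})
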