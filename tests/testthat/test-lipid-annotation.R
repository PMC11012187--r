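test_that("shorthand names parse into the documented structures", {
  sp <- parse_lipid_name("TG(4:0/18:1/18:2)")
  expect_equal(sp$subclass, "TG")
  expect_length(sp$chains, 3L)
  expect_true(sp$sn_resolved)
  expect_equal(sp$chains[[1]]$carbons, 4L)
  expect_equal(sp$chains[[3]]$double_bonds, 2L)
  expect_equal(sp$chains[[2]]$sn_index, 2L)

  ox <- parse_lipid_name("TG(16:0/18:1/18:2+OO)")
  expect_equal(ox$subclass, "TG_2OX")
  expect_equal(ox$chains[[3]]$oxygens_added, 2L)
  expect_equal(parse_lipid_name("TG(16:0/18:1+O/18:2)")$subclass, "TG_1OX")
  expect_equal(parse_lipid_name("DG(14:0/18:2+OO)")$subclass, "DG_OX")

  cer <- parse_lipid_name("Cer(d18:1/16:0)", adduct = "+HCOO")
  expect_equal(cer$subclass, "Cer")
  expect_true(cer$chains[[1]]$sphingoid)
  expect_equal(cer$ion_mode, "positive")  # +HCOO sign is +, mode from adduct text
  neg <- parse_lipid_name("PI(16:0/18:1)", adduct = "-H")
  expect_equal(neg$ion_mode, "negative")

  und <- parse_lipid_name("TG(16:0_18:1_18:2)")
  expect_false(und$sn_resolved)
  expect_true(all(is.na(vapply(und$chains, `[[`, integer(1), "sn_index"))))
})

test_that("parser failures are typed and named", {
  expect_error(parse_lipid_name("XX(1:0)"), class = "lipid_unknown_class")
  expect_error(parse_lipid_name("TG(16:0/18:1)"),
               class = "lipid_chain_count_mismatch")
  expect_error(parse_lipid_name("TG(16:0/18:1/banana)"),
               class = "lipid_malformed_chain")
  expect_error(parse_lipid_name("TG(1:0/18:1/18:2)"),
               class = "lipid_malformed_chain")   # < 2 carbons
  expect_error(parse_lipid_name("TG(16:9/18:1/18:2)"),
               class = "lipid_malformed_chain")   # impossible unsaturation
  expect_error(parse_lipid_name("TG16:0"), class = "lipid_parse_error")
})

test_that("format/parse round-trips canonical names, sorting unresolved chains", {
  expect_equal(format(parse_lipid_name("TG(4:0/18:1/18:2)")), "TG(4:0/18:1/18:2)")
  expect_equal(format(parse_lipid_name("TG(18:2_4:0_18:1)")), "TG(18:1_18:2_4:0)")
  for (nm in c("Cer(d18:1/16:0)", "TG(16:0/18:1/18:2+OO)", "LPC(18:1)",
               "ChE(18:1)", "SM(d16:1/22:0)")) {
    expect_equal(format(parse_lipid_name(format(parse_lipid_name(nm)))),
                 format(parse_lipid_name(nm)))
  }
})

test_that("fatty acyl classification follows the saturation and length taxonomies", {
  expect_equal(classify_fa(list(carbons = 18, double_bonds = 2)),
               list(saturation = "PUFA", chain_length_class = "L-C",
                    odd_chain = FALSE))
  expect_equal(classify_fa(list(carbons = 4, double_bonds = 0))$saturation, "SFA")
  expect_equal(classify_fa(list(carbons = 4, double_bonds = 0))$chain_length_class,
               "S-C")
  f15 <- classify_fa(list(carbons = 15, double_bonds = 0))
  expect_equal(f15$chain_length_class, "M-C")
  expect_true(f15$odd_chain)
  # 16:0 is long-chain under the default boundary; configurable
  expect_equal(classify_fa(list(carbons = 16, double_bonds = 0))$chain_length_class,
               "L-C")
  expect_equal(classify_fa(list(carbons = 16, double_bonds = 0),
                           lc_min = 17)$chain_length_class, "M-C")
  # total function: every chain lands in exactly one category of each taxonomy
  for (c_n in 2:26) for (d in 0:(c_n %/% 2)) {
    ann <- classify_fa(list(carbons = c_n, double_bonds = d))
    expect_true(ann$saturation %in% c("SFA", "MUFA", "PUFA"))
    expect_true(ann$chain_length_class %in% c("S-C", "M-C", "L-C"))
  }
})

test_that("the synthetic inventory reproduces the study-level tallies", {
  fix <- gen_lipid_fixture()
  s <- summarize_inventory(fix)
  expect_equal(s$n_subclasses, 18L)
  expect_gte(s$n_species, 400L)
  expect_equal(unname(s$subclass_counts["TG"]), 322L)
  expect_equal(unname(s$subclass_counts["TG_1OX"]), 13L)
  expect_equal(unname(s$subclass_counts["TG_2OX"]), 11L)
  expect_equal(unname(s$subclass_counts["DG"]), 39L)
  expect_equal(unname(s$subclass_counts["HexCer"]), 7L)
  expect_equal(unname(s$subclass_counts["SM"]), 8L)

  tg <- s$tg_positions
  expect_equal(tg[tg$position == "sn-1", c("SFA", "MUFA", "PUFA")],
               data.frame(SFA = 274L, MUFA = 48L, PUFA = 0L),
               ignore_attr = TRUE)
  expect_equal(tg[tg$position == "sn-2", c("SFA", "MUFA", "PUFA")],
               data.frame(SFA = 205L, MUFA = 101L, PUFA = 16L),
               ignore_attr = TRUE)
  expect_equal(tg[tg$position == "sn-1", "most_frequent_fa"], "4:0")
  # percentages per position partition to 100
  expect_equal(rowSums(tg[, c("pct_SC", "pct_MC", "pct_LC")]), rep(100, 3),
               ignore_attr = TRUE)

  dg <- s$dg_positions
  expect_equal(round(100 * dg$SFA[1] / dg$n[1]), 87)
  expect_equal(round(100 * dg$MUFA[1] / dg$n[1]), 13)
  expect_equal(dg$PUFA[1], 0L)

  # SM all +HCOO, negative mode
  sm <- Filter(function(x) x$subclass == "SM", fix)
  expect_true(all(vapply(sm, `[[`, character(1), "adduct") == "+HCOO"))
  expect_true(all(vapply(sm, `[[`, character(1), "ion_mode") == "negative"))

  # oxidized species: all graded A/B; six have a non-oxidized parent
  ox <- Filter(function(x) x$subclass %in% c("TG_1OX", "TG_2OX", "DG_OX"), fix)
  expect_true(all(vapply(ox, `[[`, character(1), "grade") %in% c("A", "B")))
  expect_equal(sum(s$oxidized_parents$has_parent), 6L)
  # parser round-trip on every fixture name
  for (sp in fix) {
    expect_equal(format(parse_lipid_name(format(sp))), format(sp))
  }
})

test_that("an empty and a singleton inventory summarize sensibly", {
  s0 <- summarize_inventory(list())
  expect_equal(s0$n_species, 0L)
  s1 <- summarize_inventory(list(parse_lipid_name("LPC(16:0)", adduct = "+H")))
  expect_equal(unname(s1$subclass_counts), 1L)
  expect_equal(s1$n_subclasses, 1L)
})

test_that("method comparison matches brute-force set algebra", {
  fix <- gen_lipid_fixture()
  a <- fix[1:60]
  b <- fix[31:90]
  cmp <- compare_methods(a, b)
  key <- function(t) vapply(t, function(s) paste0(format(s), "|", s$ion_mode),
                            character(1))
  expect_equal(sum(cmp$counts$shared), length(intersect(key(a), key(b))))
  expect_equal(sum(cmp$counts$unique_a), length(setdiff(key(a), key(b))))
  expect_equal(sum(cmp$counts$unique_b), length(setdiff(key(b), key(a))))

  ident <- compare_methods(a, a)
  expect_true(all(ident$counts$unique_a == 0))
  expect_true(all(ident$counts$unique_b == 0))
  expect_equal(ident$counts$count_a, ident$counts$shared)

  extra <- c(a, list(parse_lipid_name("LPS(17:0)", adduct = "-H"),
                     parse_lipid_name("LPS(15:0)", adduct = "-H")))
  cmp2 <- compare_methods(a, extra)
  expect_equal(cmp2$counts$unique_b[cmp2$counts$subclass == "LPS"], 2L)

  set.seed(70)
  for (i in 1:25) {
    ia <- sample(length(fix), 40); ib <- sample(length(fix), 40)
    cc <- compare_methods(fix[ia], fix[ib])
    expect_equal(sum(cc$counts$shared),
                 length(intersect(key(fix[ia]), key(fix[ib]))))
  }
})

test_that("QC gating applies the strict RSD threshold", {
  r <- qc_check(list(stable = c(100, 100, 100)))
  expect_equal(r$rsd_pct, 0)
  expect_true(r$pass)
  r2 <- qc_check(list(wobbly = c(80, 120)))
  expect_equal(r2$rsd_pct, 100 * stats::sd(c(80, 120)) / 100)
  expect_equal(round(r2$rsd_pct, 1), 28.3)
  expect_false(r2$pass)
  # exactly at the threshold fails (strict inequality)
  r3 <- qc_check(list(edge = c(100 - 10 * sqrt(2), 100 + 10 * sqrt(2))))
  expect_equal(r3$rsd_pct, 20)
  expect_false(r3$pass)
  expect_true(qc_check(list(edge = c(100 - 10 * sqrt(2), 100 + 10 * sqrt(2))),
                       threshold_pct = 20.0001)$pass)
  zero <- qc_check(list(null = c(-5, 5)))
  expect_false(zero$pass)
  expect_match(zero$reason, "undefined")
  expect_error(qc_check(list(single = 5)), "at least 2")
})

test_that("identification tables round-trip through files with failure reporting", {
  fix <- gen_lipid_fixture()[1:25]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lipid_table(fix, path, areas = seq_along(fix))
  back <- read_lipid_table(path)
  expect_length(back$species, 25L)
  expect_null(back$failures)
  expect_equal(vapply(back$species, format, character(1)),
               vapply(fix, format, character(1)))
  # inject a broken and an unknown-class row
  lines <- readLines(path)
  writeLines(c(lines, "XX(1:0)\t+H\tpositive\tA\t1",
               "TG(16:0/18:1)\t+H\tpositive\tA\t1"), path)
  back2 <- read_lipid_table(path)
  expect_equal(nrow(back2$failures), 2L)
  expect_length(back2$species, 25L)
  # grade filter
  ab <- read_lipid_table(path, grades = "A")
  expect_true(all(vapply(ab$species, `[[`, character(1), "grade") == "A"))
})
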