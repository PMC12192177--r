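test_that("property averaging reduces to single-residue vectors on homopolymers", {
  t1 <- RES$aaindex
  f <- encode_aaindex("AAAA", t1)
  expect_identical(length(f), t1$n_properties)
  expect_equal(as.numeric(unclass(f)), unname(t1$values[, "A"]))
  # two residues: element-wise mean
  f2 <- encode_aaindex("AC", t1)
  expect_equal(as.numeric(unclass(f2)),
               unname((t1$values[, "A"] + t1$values[, "C"]) / 2))
})

test_that("CTD composition, transition and distribution follow their formulas", {
  g <- RES$ctd
  hom <- encode_ctd("GGGGG", g)
  expect_identical(length(hom), 273L)
  for (p in g$properties) {
    grp <- g$groups[[p]][["G"]]
    comp <- unclass(hom)[paste0("ctd.", p, ".C", 1:3)]
    expect_equal(unname(comp), as.numeric(1:3 == grp))
    expect_equal(unname(unclass(hom)[paste0("ctd.", p, ".", c("T12", "T13", "T23"))]),
                 c(0, 0, 0))
  }
  # alternating two-group sequence: every adjacent pair is a transition
  seq <- "ARARAR"
  enc <- unclass(encode_ctd(seq, g))
  for (p in g$properties) {
    ga <- g$groups[[p]][["A"]]; gr <- g$groups[[p]][["R"]]
    if (ga == gr) next
    pair <- paste0("T", min(ga, gr), max(ga, gr))
    expect_equal(unname(enc[paste0("ctd.", p, ".", pair)]), 1)
    others <- setdiff(c("T12", "T13", "T23"), pair)
    expect_equal(unname(enc[paste0("ctd.", p, ".", others)]), c(0, 0))
  }
  # distribution milestones on a hand-worked case: property 'charge',
  # sequence KKDKA -> group1 (K,R) at positions 1,2,4; L = 5
  ch <- unclass(encode_ctd("KKDKA", g))
  expect_equal(unname(ch[paste0("ctd.charge.D1.p", c(0, 25, 50, 75, 100))]),
               c(1, 1, 2, 4, 4) / 5)
  # group 3 (D,E) occurs once at position 3: all milestones there
  expect_equal(unname(ch[paste0("ctd.charge.D3.p", c(0, 25, 50, 75, 100))]),
               rep(3 / 5, 5))
})

test_that("CTD structural invariants hold on random peptides", {
  ds <- generate_dataset(synthesis_config(n_pos = 15, n_neg = 15, seed = 5))
  for (s in ds$seq) {
    enc <- unclass(encode_ctd(s, RES$ctd))
    for (p in RES$ctd$properties) {
      expect_equal(sum(enc[paste0("ctd.", p, ".C", 1:3)]), 1)
      expect_lte(sum(enc[paste0("ctd.", p, ".", c("T12", "T13", "T23"))]), 1 + 1e-12)
    }
    expect_true(all(enc >= 0 & enc <= 1))
  }
})

test_that("the printed-formula distribution variant is available for audit", {
  enc <- unclass(encode_ctd("KKDKA", RES$ctd, d_variant = "cumulative"))
  # charge group 1 at positions 1,2,4 of 5: shares within the first
  # ceiling(k% * L) positions (0, 2, 3, 4, 5) are 0/3, 2/3, 2/3, 3/3, 3/3
  expect_equal(unname(enc[paste0("ctd.charge.D1.p", c(0, 25, 50, 75, 100))]),
               c(0, 2, 2, 3, 3) / 3)
})

test_that("skip dipeptide composition is a probability vector matching brute force", {
  one <- unclass(encode_asdc("AC"))
  expect_identical(length(one), 400L)
  expect_equal(unname(one["asdc.AC"]), 1)
  expect_equal(sum(one), 1)

  tri <- unclass(encode_asdc("ACA"))
  expect_equal(unname(tri[c("asdc.AC", "asdc.AA", "asdc.CA")]), rep(1 / 3, 3))

  # oracle equivalence: every peptide of length 2..5 over {A, C, D}
  sub <- c("A", "C", "D")
  for (L in 2:5) {
    grid <- do.call(expand.grid, rep(list(sub), L))
    seqs <- apply(grid, 1, paste, collapse = "")
    for (s in seqs) {
      expect_equal(as.numeric(unclass(encode_asdc(s))), unname(asdc_oracle(s)))
    }
  }
})

test_that("substitution-profile encoding weights matrix rows by residue frequency", {
  m <- RES$blosum62
  hom <- unclass(encode_blosum62("AAAA", m))
  expect_identical(length(hom), 420L)
  expect_equal(unname(hom[1:21]), as.numeric(m["A", ]))
  expect_equal(unname(hom[22:420]), rep(0, 399))

  ac <- unclass(encode_blosum62("AC", m))
  expect_equal(unname(ac[1:21]), 0.5 * as.numeric(m["A", ]))
  cpos <- 21 + 1:21  # C is the second residue alphabetically
  expect_equal(unname(ac[cpos]), 0.5 * as.numeric(m["C", ]))
  expect_equal(unname(ac[-c(1:21, cpos)]), rep(0, 420 - 42))
})

test_that("composition-only encoders are invariant to residue repetition", {
  # 'ACD' and 'AACCDD' have identical composition
  for (enc in list(function(s) encode_aaindex(s, RES$aaindex),
                   function(s) encode_blosum62(s, RES$blosum62))) {
    expect_equal(unclass(enc("ACD")), unclass(enc("AACCDD")))
  }
  # ...but the pair-based encoder is not
  expect_false(isTRUE(all.equal(unclass(encode_asdc("ACD")),
                                unclass(encode_asdc("AACCDD")))))
})

test_that("encoders are pure: identical inputs give bit-identical outputs", {
  s <- "GSHWYKDE"
  expect_identical(encode_fusion(s, c("aaindex", "asdc", "blosum62", "ctd"), RES),
                   encode_fusion(s, c("aaindex", "asdc", "blosum62", "ctd"), RES))
})

test_that("fusion concatenates members in canonical order with stable dims", {
  s <- "GSHWYK"
  fb <- encode_fusion(s, c("ctd", "blosum62"), RES)
  expect_identical(length(fb), 693L)
  # order given by the user does not matter
  expect_identical(fb, encode_fusion(s, c("blosum62", "ctd"), RES))
  expect_identical(names(fb)[1], "blosum62.A.A")  # blosum62 precedes ctd
  # singleton fusion is the encoder itself
  expect_equal(unclass(encode_fusion(s, "asdc", RES)), unclass(encode_asdc(s)))
  all4 <- encode_fusion(s, c("asdc", "ctd", "aaindex", "blosum62"), RES)
  expect_identical(length(all4), RES$aaindex$n_properties + 400L + 420L + 273L)
  expect_error(encode_fusion(s, c("ctd", "nope"), RES), "unknown encoder")
})

test_that("feature-set enumeration lists singletons first, then by size", {
  sets <- enumerate_feature_sets()
  expect_identical(length(sets), 15L)
  expect_identical(sum(lengths(sets) >= 2), 11L)
  expect_identical(lengths(sets), c(rep(1L, 4), rep(2L, 6), rep(3L, 4), 4L))
  expect_identical(length(enumerate_feature_sets(c("ctd"))), 1L)
  expect_identical(length(enumerate_feature_sets(c("asdc", "ctd", "blosum62"))), 7L)
  expect_error(enumerate_feature_sets(character()), "non-empty")
  expect_error(enumerate_feature_sets(c("ctd", "ctd")), "duplicates")
})
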