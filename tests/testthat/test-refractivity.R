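# FASTA ingestion, composition, dn/dc computation and summaries.

test_that("parse_fasta reads, sanitizes and round-trips", {
  p <- tempfile(fileext = ".fasta")
  writeLines(c(">prot1 lens crystallin", "MKTAYIAKQR",
               ">prot2", "MX*A-GB"), p)
  expect_message(rec <- parse_fasta(p), "dropped 4")
  expect_identical(rec$id, c("prot1", "prot2"))
  expect_identical(rec$sequence[2], "MAG")
  expect_identical(rec$n_dropped, c(0L, 4L))

  # round trip preserves id and sequence
  p2 <- tempfile(fileext = ".fasta")
  writeLines(c(">prot1", rec$sequence[1]), p2)
  rec2 <- parse_fasta(p2)
  expect_identical(rec2$sequence, rec$sequence[1])

  p3 <- tempfile(fileext = ".fasta")
  writeLines(c(">allbad", "XXX**"), p3)
  expect_error(suppressMessages(parse_fasta(p3)), "empty after sanitization")
})

test_that("residue_composition counts residues and is order-insensitive", {
  comp <- residue_composition("GGG")
  expect_identical(unname(comp[["G"]]), 3L)
  expect_identical(sum(comp), 3L)

  all20 <- "ACDEFGHIKLMNPQRSTVWY"
  expect_true(all(residue_composition(all20) == 1L))

  perm <- paste(sample(strsplit(all20, "")[[1]]), collapse = "")
  expect_identical(residue_composition(perm), residue_composition(all20))

  expect_error(residue_composition("MAXB"), "non-standard")
})

test_that("homopolymer dn/dc equals the residue-level table value", {
  tab <- residue_refractivity()
  for (r in c("G", "W", "A", "F")) {
    homo <- strrep(r, 25)
    expect_equal(protein_dndc(homo)$dndc, tab[r, "dndc"], tolerance = 1e-9)
  }
})

test_that("dn/dc matches the independent spreadsheet oracle", {
  seqs <- c(strrep("GAVL", 50),
            "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
            gen_protein(residue_profiles()$gamma_like, 200, seed = 4)$sequence)
  for (s in seqs) {
    expect_equal(protein_dndc(s)$dndc, oracle_dndc(s), tolerance = 1e-6)
  }
  # at a different solvent index too
  expect_equal(protein_dndc(seqs[1], solvent_n = 1.40)$dndc,
               oracle_dndc(seqs[1], solvent_n = 1.40), tolerance = 1e-6)
})

test_that("dn/dc depends only on composition and is convex under concatenation", {
  s <- gen_protein(residue_profiles()$natural, 120, seed = 8)$sequence
  perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(protein_dndc(s)$dndc, protein_dndc(perm)$dndc,
               tolerance = 1e-12)

  s2 <- gen_protein(residue_profiles()$gamma_like, 150, seed = 9)$sequence
  d1 <- protein_dndc(s)$dndc
  d2 <- protein_dndc(s2)$dndc
  dcat <- protein_dndc(paste0(s, s2))$dndc
  expect_gte(dcat, min(d1, d2) - 1e-9)
  expect_lte(dcat, max(d1, d2) + 1e-9)
})

test_that("dn/dc of natural-composition proteins stays in the sanity band", {
  vals <- vapply(1:1000, function(i) {
    protein_dndc(gen_protein(residue_profiles()$natural, 180,
                             seed = i)$sequence)$dndc
  }, 0)
  expect_true(all(vals > 0.17))
  expect_true(all(vals < 0.22))
})

test_that("conditions are recorded and inputs validated", {
  r <- protein_dndc("MKTAY")
  expect_equal(r$conditions$wavelength_nm, 589)
  expect_equal(r$conditions$temperature_c, 25)
  expect_equal(r$conditions$solvent_n, 1.3340)
  expect_error(protein_dndc(c(Z = 5)), "missing from refractivity table")
})

test_that("class means and weighted means behave as stated", {
  recs <- do.call(rbind, lapply(1:20, function(i) {
    gen_protein(residue_profiles()$natural, 100, id = paste0("p", i),
                seed = 200 + i)
  }))
  cls <- rep(c("alpha", "beta", "gamma", "other"), 5)
  tab <- dndc_table(recs, stats::setNames(cls, recs$id))
  cm <- class_mean_dndc(tab)
  # brute-force recomputation
  for (k in unique(cls)) {
    expect_equal(cm$mean_dndc[cm$crystallin_class == k],
                 mean(tab$dndc[tab$crystallin_class == k]), tolerance = 1e-12)
  }
  # one protein per class: mean equals that protein's value
  one <- tab[1:4, ]
  one$crystallin_class <- c("a", "b", "c", "d")
  cm1 <- class_mean_dndc(one)
  expect_equal(sort(cm1$mean_dndc), sort(one$dndc))
  expect_warning(class_mean_dndc(rbind(tab, data.frame(
    id = "x", crystallin_class = NA, dndc = 0.2))), "omitted")

  d <- c(0.19, 0.20, 0.21)
  expect_equal(weighted_mean_dndc(d, c(1, 1, 1)), mean(d))
  expect_equal(weighted_mean_dndc(d, c(0, 5, 0)), 0.20)
  expect_equal(weighted_mean_dndc(d, c(2, 3, 4)),
               weighted_mean_dndc(d, c(2, 3, 4) * 1000), tolerance = 1e-12)
  expect_error(weighted_mean_dndc(d, c(0, 0, 0)), "zero")
  expect_error(weighted_mean_dndc(d, c(-1, 1, 1)), "nonnegative")
})

test_that("gamma-like compositions have higher dn/dc than alpha-like ones", {
  g <- vapply(1:100, function(i) {
    protein_dndc(gen_protein(residue_profiles()$gamma_like, 180,
                             seed = i)$sequence)$dndc
  }, 0)
  a <- vapply(1:100, function(i) {
    protein_dndc(gen_protein(residue_profiles()$alpha_like, 180,
                             seed = 3000 + i)$sequence)$dndc
  }, 0)
  expect_gt(mean(g), mean(a))
})
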