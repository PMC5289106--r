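test_that("IUPAC expansion gives canonical state-sets", {
  y <- expand_iupac("Y")
  expect_equal(y$bases, c("C", "T"))
  expect_equal(y$kind, "standard")
  expect_equal(expand_iupac("N")$kind, "missing")
  expect_equal(expand_iupac("?")$kind, "missing")
  expect_equal(expand_iupac("-")$kind, "gap")
  expect_equal(expand_iupac("u")$bases, "T")
  expect_equal(expand_iupac("3")$kind, "indel2isp")
  expect_error(expand_iupac("X"), "unknown")
})

test_that("symbol -> state-set mapping is injective up to the N/? synonym", {
  syms <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
            "V", "H", "D", "B", "-")
  codes <- vapply(syms, function(s) expand_iupac(s)$code, integer(1))
  expect_equal(anyDuplicated(codes), 0L)
  # the two missing spellings collapse onto one canonical set
  expect_equal(expand_iupac("N")$code, expand_iupac("?")$code)
  # round trip through the canonical symbol
  expect_equal(unname(iupac_symbol(codes)), syms)
})

test_that("alignments are validated on construction and read", {
  a <- twoisp_alignment(c(s1 = "ACGT", s2 = "ACYT"))
  expect_equal(a$length, 4L)
  summ <- twoisp_site_summary(a)
  expect_equal(sum(summ$sites$n_2isp), 1)
  expect_equal(which(summ$sites$n_2isp == 1), 3L)
  expect_error(twoisp_alignment(c(s1 = "ACGT", s2 = "ACGTA")),
               "alignment-shape")
  expect_error(twoisp_alignment(c(s1 = "ACGT", s1 = "ACGT")), "unique")
  expect_error(twoisp_alignment(c(s1 = "ACXT", s2 = "ACGT")),
               "column 3")
})

test_that("FASTA round trip reproduces every state-set", {
  path <- withr::local_tempfile(fileext = ".fasta")
  a <- twoisp_alignment(c(p1 = "ACYTN-R5", p2 = "acgt?-r5", p3 = "AAAAAAAA"),
                        locus = "demo")
  write_alignment(a, path)
  b <- read_alignment(path, locus = "demo")
  expect_identical(unname(b$states), unname(a$states))
  expect_identical(b$ids, a$ids)
})

test_that("per-site summary distinguishes 2ISPs, missing and monomorphy", {
  a <- twoisp_alignment(c(x = "CCN", y = "YCN", z = "CCN"))
  s <- twoisp_site_summary(a)$sites
  # column 1: states {C},{C,T},{C} -> one 2ISP, two state-sets, segregating
  expect_equal(s$n_2isp[1], 1)
  expect_equal(s$n_states[1], 2)
  expect_true(s$is_segregating[1])
  # column 2 identical -> not segregating
  expect_equal(s$n_2isp[2], 0)
  expect_false(s$is_segregating[2])
  # column 3 all missing -> no observable states
  expect_equal(s$n_states[3], 0)
  expect_false(s$is_segregating[3])
  expect_equal(twoisp_site_summary(a)$per_sequence$n_2isp, c(0, 1, 0))
})

test_that("simple indel coding creates one character per shared gap run", {
  a <- code_indels(twoisp_alignment(c(s1 = "AC--T", s2 = "ACGGT", s3 = "AC--T")))
  expect_equal(ncol(a$indels), 1L)
  expect_equal(unname(a$indels[, 1]), c(1L, 0L, 1L))
  expect_equal(a$site_use, c(TRUE, TRUE, FALSE, FALSE, TRUE))
  # coded columns drop out of the site distance; the character contributes
  d <- genetic_distance_matrix(a)
  expect_equal(d["s1", "s2"], 1 / 4)
  expect_equal(d["s1", "s3"], 0)
})

test_that("gap runs beside homopolymer repeats are not coded", {
  a <- code_indels(twoisp_alignment(c(s1 = "AAAAGC", s2 = "AAAA-C")))
  expect_equal(ncol(a$indels), 0L)
  # with a shorter flank the same gap is coded
  b <- code_indels(twoisp_alignment(c(s1 = "TAAGGC", s2 = "TAA-GC")),
                   homopolymer_min = 4L)
  expect_equal(ncol(b$indels), 1L)
  # and a stricter threshold can re-admit the homopolymer-adjacent gap
  cc <- code_indels(twoisp_alignment(c(s1 = "AAAAGC", s2 = "AAAA-C")),
                    homopolymer_min = 5L)
  expect_equal(ncol(cc$indels), 1L)
})

test_that("indel coding is idempotent and bounded by distinct gap patterns", {
  seqs <- c(a = "AC--TG-A", b = "ACGGTG-A", c = "AC--T--A", d = "ACGGTGGA")
  a1 <- code_indels(twoisp_alignment(seqs))
  a2 <- code_indels(a1)
  expect_identical(a1$indels, a2$indels)
  expect_identical(a1$site_use, a2$site_use)
  pat <- unique(do.call(rbind, lapply(strsplit(seqs, ""), function(ch) {
    r <- rle(ch == "-")
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1L
    cbind(s[r$values], e[r$values])
  })))
  expect_lte(ncol(a1$indels), nrow(pat))
})

test_that("sequences with a longer covering gap score missing for the sub-run", {
  a <- code_indels(twoisp_alignment(c(s1 = "AC--TA", s2 = "AC---A",
                                      s3 = "ACGGTA")))
  # runs (3,4) and (3,5) are separate characters
  expect_equal(ncol(a$indels), 2L)
  k <- which(colnames(a$indels) == "indel_3_4")
  expect_true(is.na(a$indels["s2", k]))
  expect_equal(a$indels["s3", k], 0L)
})

test_that("sample rules reassign and exclude without dropping rows", {
  tab <- as_sample_table(data.frame(
    sample_id = c("AJP0100", "AJP0200", "AJP0537", "AJP0810", "OUT1"),
    group = c("Gamtoos", "Sundays", "Gamtoos", "Gamtoos", NA),
    lat = c(-33.5, -33.4, -33.45, -33.46, -30),
    lon = c(24.5, 25.0, 24.9, 24.91, 18),
    role = c(rep("ingroup", 4), "outgroup")))
  rules <- rule_set(
    reassignments = data.frame(sample_id = "AJP0100", new_group = "Sundays",
                               reason = "within 5 km of watershed"),
    exclusions = data.frame(sample_id = c("AJP0537", "AJP0810"),
                            reason = "contact zone"))
  out <- apply_sample_rules(tab, rules)
  expect_equal(nrow(out), nrow(tab))
  expect_equal(out$group[out$sample_id == "AJP0100"], "Sundays")
  expect_equal(out$reassigned_from[out$sample_id == "AJP0100"], "Gamtoos")
  expect_equal(sum(out$excluded), 2)
  # ingroup count for analyses drops by the two exclusions
  expect_equal(length(phylocatch:::.active_samples(out)),
               length(phylocatch:::.active_samples(tab)) - 2)
  # input untouched; empty rule set is the identity
  expect_equal(sum(tab$excluded), 0)
  expect_identical(apply_sample_rules(tab, rule_set()), tab)
  expect_error(apply_sample_rules(tab, rule_set(
    exclusions = data.frame(sample_id = "NOPE", reason = "x"))),
    "unknown sample")
  expect_error(rule_set(
    reassignments = data.frame(sample_id = "A", new_group = "B", reason = "r"),
    exclusions = data.frame(sample_id = "A", reason = "r")),
    "both")
})
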