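test_that("configs validate their demographic parameters", {
  expect_s3_class(tiny_sim_config(), "sim_config")
  expect_error(sim_config(K = 3, split_times = c(2e6, 1e6)), "increasing")
  expect_error(sim_config(K = 2, split_times = numeric(0)), "length")
  expect_error(sim_config(Ne = -1, K = 1, split_times = numeric(0)))
})

test_that("single-population TMRCA matches the coalescent expectation", {
  cfg <- sim_config(K = 1, split_times = numeric(0), n_per_catchment = 5,
                    Ne = 100, generation_time = 1,
                    loci = list(list(name = "l", L = 100, mu = 1e-6, copies = 1)),
                    seed = 2)
  set.seed(2)
  tm <- replicate(1000, {
    tr <- simulate_genealogy(cfg)
    max(ape::node.depth.edgelength(tr))
  })
  # E[TMRCA] = 4 Ne (1 - 1/n) generations
  expected <- 4 * 100 * (1 - 1 / 5)
  expect_lt(abs(mean(tm) - expected) / expected, 0.05)
})

test_that("lineages from different catchments only coalesce past the split", {
  cfg <- sim_config(K = 2, split_times = 1e6, n_per_catchment = 4,
                    Ne = 3000, generation_time = 10,
                    loci = list(list(name = "l", L = 100, mu = 1e-9, copies = 1)),
                    seed = 3)
  set.seed(3)
  for (rep in 1:10) {
    tr <- simulate_genealogy(cfg)
    cp <- ape::cophenetic.phylo(tr)
    a <- grep("catchment_1", rownames(cp))
    b <- grep("catchment_2", rownames(cp))
    # pairwise time to coalescence = half the path length, in years
    expect_true(all(cp[a, b] / 2 >= 1e6 - 1e-6))
  }
})

test_that("fixed seeds reproduce genealogies and datasets exactly", {
  cfg <- tiny_sim_config(seed = 4L)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(lapply(s1$alignments, `[[`, "states"),
                   lapply(s2$alignments, `[[`, "states"))
  expect_identical(ape::write.tree(s1$genealogies$cp),
                   ape::write.tree(s2$genealogies$cp))
  expect_identical(s1$table, s2$table)
})

test_that("segregating sites track the Watterson expectation", {
  n <- 8; Ne <- 500; mu <- 1e-5; L <- 500
  cfg <- sim_config(K = 1, split_times = numeric(0), n_per_catchment = n,
                    Ne = Ne, generation_time = 1,
                    loci = list(list(name = "l", L = L, mu = mu, copies = 1)),
                    seed = 6)
  set.seed(6)
  s_vals <- replicate(300, {
    tr <- simulate_genealogy(cfg)
    seqs <- drop_mutations(tr, mu, L)
    a <- twoisp_alignment(seqs)
    segregating_sites(a)
  })
  expected <- 4 * Ne * mu * L * sum(1 / seq_len(n - 1))
  expect_lt(abs(mean(s_vals) - expected) / expected, 0.1)
})

test_that("mutation placement respects the infinite-sites bound", {
  tr <- ape::read.tree(text = "(a:0,b:0);")
  seqs <- drop_mutations(tr, 1e-9, 50)
  expect_equal(unname(seqs["a"]), unname(seqs["b"]))
  big <- ape::read.tree(text = "(a:1e9,b:1e9);")
  expect_error(drop_mutations(big, 1e-3, 10), "more mutations")
})

test_that("copy collapse produces the IUPAC union per site", {
  expect_equal(collapse_to_2isp(c("CCA", "TCA")), "YCA")
  expect_equal(collapse_to_2isp(c("ACGT", "ACGT")), "ACGT")
  expect_equal(collapse_to_2isp(c("A", "G", "G")), "R")
  expect_equal(collapse_to_2isp("ACGT"), "ACGT")
  expect_error(collapse_to_2isp(c("AC", "A")), "length")
  # faster-mutating copies carry more 2ISPs (greater copy divergence)
  n2isp <- vapply(c(1e-9, 2e-8), function(m) {
    cfg <- tiny_sim_config(seed = 21L,
                           loci = list(list(name = "nuc", L = 800, mu = m,
                                            copies = 3)))
    sim <- simulate_dataset(cfg)
    sum(twoisp_site_summary(sim$alignments$nuc)$sites$n_2isp)
  }, numeric(1))
  expect_gt(n2isp[2], n2isp[1])
})

test_that("localities sit in their catchment band with enforced spacing", {
  cfg <- tiny_sim_config(seed = 8L)
  set.seed(8)
  loc <- simulate_localities(cfg)
  expect_equal(nrow(loc), 15)
  # west-to-east arrangement of catchment bands
  means <- tapply(loc$lon, loc$group, mean)[cfg$labels]
  expect_true(all(diff(means) > 0))
  d <- geographic_distance_matrix(as_sample_table(data.frame(loc, role = "ingroup")))
  expect_gte(min(d[upper.tri(d)]), cfg$min_spacing_km)
  expect_error({
    set.seed(1)
    simulate_localities(tiny_sim_config(n_per_catchment = 400))
  }, "too small")
})

test_that("LGM grids contract and fragment within every catchment", {
  cfg <- tiny_sim_config(seed = 10L)
  set.seed(10)
  sdm <- simulate_sdm(cfg)
  expect_equal(length(sdm$ensemble_current), cfg$n_models)
  thr <- sdm$threshold
  bc <- binarize(sdm$current, thr)
  bl <- binarize(sdm$lgm, thr)
  for (mk in sdm$masks) {
    cur <- patch_metrics(bc, mk, scenario = "current")
    lgm <- patch_metrics(bl, mk, scenario = "LGM")
    expect_lt(lgm$area_cells, cur$area_cells)
  }
  # ensemble agreement peaks at the kernel centres
  ag <- ensemble_agreement(sdm$ensemble_current)$values
  centre <- ag[nrow(ag) / 2, round((1 - 0.5) * ncol(ag) / cfg$K)]
  corner <- ag[1, 1]
  expect_gt(centre, corner)
  expect_equal(max(ag), 1)
})

test_that("fixture directories are byte-identical under one seed", {
  cfg <- tiny_sim_config(seed = 12L, n_models = 4)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture_set(simulate_dataset(cfg), d1)
  write_fixture_set(simulate_dataset(cfg), d2)
  files <- list.files(d1)
  expect_true(all(c("cp.fasta", "nuc.fasta", "samples.tsv", "manifest.json",
                    "suitability_current.asc", "suitability_lgm.asc") %in% files))
  expect_identical(files, list.files(d2))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$seed, 12L)
  expect_equal(man$K, 3)
})
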