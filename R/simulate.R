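#' Simulation configuration for catchment-structured data
#'
#' Defines the demographic and landscape scenario the synthetic data
#' emulate: K catchment populations that split sequentially (west to
#' east), each locus evolving on its own coalescent genealogy under
#' infinite sites, multi-copy nuclear loci collapsing to IUPAC 2ISP
#' consensus sequences, localities clustered per catchment, and paired
#' current/LGM suitability grids where the LGM range contracts and
#' fragments within each catchment.
#'
#' Defaults describe a scenario of three deeply split catchments with
#' Pleistocene divergence: `Ne = 5000`, generation time 10 years (a
#' slow-maturing perennial), splits at 0.8 and 1.5 Ma, a slow-evolving
#' single-copy chloroplast locus and faster multi-copy nuclear loci.
#'
#' @param K number of catchments.
#' @param n_per_catchment individuals sampled per catchment.
#' @param split_times increasing vector of K-1 merge times in years
#'   (rootward): `split_times[i]` merges catchment `i+1` into the
#'   ancestral pool of catchments `1..i`.
#' @param Ne effective population size per catchment.
#' @param generation_time years per generation.
#' @param migration_rate per-lineage per-generation migration rate
#'   between extant pools (default 0: strict isolation).
#' @param loci list of locus definitions: each a list with `name`,
#'   `L` (bp), `mu` (substitutions/site/year), `copies` (intra-individual
#'   copy number; >= 2 yields 2ISPs).
#' @param contact_fraction probability that the first sample of an
#'   eastern catchment carries one nuclear copy drawn from its western
#'   neighbour (a contact-zone signal).
#' @param grid_nrow,grid_ncol,grid_cellsize_km suitability grid shape.
#' @param n_models pseudo-ensemble size for the SDM stack (default 216).
#' @param min_spacing_km minimum distance between sampled localities.
#' @param seed integer seed making every component reproducible.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(K = 3,
                       n_per_catchment = 12,
                       split_times = c(0.8e6, 1.5e6),
                       Ne = 5000,
                       generation_time = 10,
                       migration_rate = 0,
                       loci = list(
                         list(name = "cpDNA", L = 1948, mu = 1e-9, copies = 1),
                         list(name = "ITS", L = 666, mu = 8e-9, copies = 4),
                         list(name = "ncpGS", L = 1089, mu = 1e-9, copies = 2)),
                       contact_fraction = 0,
                       grid_nrow = 40, grid_ncol = 60, grid_cellsize_km = 5,
                       n_models = 216,
                       min_spacing_km = 10,
                       seed = 1L) {
  stopifnot(K >= 1, length(split_times) == K - 1, Ne > 0,
            generation_time > 0, migration_rate >= 0)
  if (K > 1 && is.unsorted(split_times, strictly = TRUE))
    stop("split_times must be strictly increasing", call. = FALSE)
  for (lc in loci) stopifnot(lc$L >= 1, lc$mu > 0, lc$copies >= 1)
  labels <- if (K == 3) c("Gouritz", "Gamtoos", "Sundays")
            else paste0("catchment_", seq_len(K))
  structure(list(K = K, n_per_catchment = n_per_catchment,
                 split_times = split_times, Ne = Ne,
                 generation_time = generation_time,
                 migration_rate = migration_rate, loci = loci,
                 contact_fraction = contact_fraction,
                 grid_nrow = grid_nrow, grid_ncol = grid_ncol,
                 grid_cellsize_km = grid_cellsize_km,
                 n_models = n_models, min_spacing_km = min_spacing_km,
                 labels = labels, seed = as.integer(seed)),
            class = "sim_config")
}

.sample_ids <- function(cfg) {
  unlist(lapply(seq_len(cfg$K), function(k)
    sprintf("%s_%02d", cfg$labels[k], seq_len(cfg$n_per_catchment))))
}

#' Simulate a structured-coalescent genealogy
#'
#' Runs the n-coalescent within each catchment (pairwise coalescence
#' rate `1/(2 Ne)` per generation, so `choose(k, 2) / (2 Ne)` for k
#' lineages), with lineages allowed to merge between catchments only
#' rootward of the corresponding split time. Optional symmetric migration
#' moves lineages between extant pools. Branch lengths are in years.
#'
#' @param cfg a [sim_config()].
#' @param copies intra-individual copy number for this locus; with
#'   `copies >= 2` each individual contributes that many tips, labelled
#'   `id.1`, `id.2`, ...
#' @return a rooted `phylo` genealogy with branch lengths in years.
#' @export
simulate_genealogy <- function(cfg, copies = 1) {
  gen <- cfg$generation_time
  tip_labels <- character(0)
  pool <- integer(0)
  for (k in seq_len(cfg$K)) {
    ids <- sprintf("%s_%02d", cfg$labels[k], seq_len(cfg$n_per_catchment))
    if (copies > 1)
      ids <- as.vector(t(outer(ids, seq_len(copies), paste, sep = ".")))
    tip_labels <- c(tip_labels, ids)
    pool <- c(pool, rep(k, length(ids)))
  }
  # per active lineage: Newick subtree fragment and node time (generations)
  sub <- as.list(tip_labels)
  tm <- numeric(length(sub))
  merges_gen <- cfg$split_times / gen
  n_merged <- 0L
  tau <- 0
  while (length(sub) > 1L) {
    # pools 1..n_merged+1 have merged into pool 1; pools beyond are extant
    extant <- c(1L, if (n_merged + 2L <= cfg$K) (n_merged + 2L):cfg$K)
    kc <- vapply(extant, function(p) sum(pool == p), numeric(1))
    rate_coal <- kc * (kc - 1) / (4 * cfg$Ne)
    rate_mig <- if (length(extant) > 1L) kc * cfg$migration_rate
                else numeric(length(extant))
    total <- sum(rate_coal) + sum(rate_mig)
    t_next_merge <- if (n_merged < cfg$K - 1L) merges_gen[n_merged + 1L] else Inf
    dt <- if (total > 0) rexp(1, total) else Inf
    if (tau + dt >= t_next_merge) {
      tau <- t_next_merge
      pool[pool == n_merged + 2L] <- 1L
      n_merged <- n_merged + 1L
      next
    }
    tau <- tau + dt
    u <- runif(1) * total
    for (pi in seq_along(extant)) {
      if (u <= rate_coal[pi]) {
        pair <- sample(which(pool == extant[pi]), 2)
        a <- pair[1]; b <- pair[2]
        sub[[a]] <- sprintf("(%s:%.8e,%s:%.8e)", sub[[a]],
                            (tau - tm[a]) * gen, sub[[b]],
                            (tau - tm[b]) * gen)
        tm[a] <- tau
        keep <- setdiff(seq_along(sub), b)
        sub <- sub[keep]; tm <- tm[keep]; pool <- pool[keep]
        break
      }
      u <- u - rate_coal[pi]
      if (u <= rate_mig[pi]) {
        members <- which(pool == extant[pi])
        ln <- members[sample.int(length(members), 1)]
        dest <- setdiff(extant, extant[pi])
        pool[ln] <- dest[sample.int(length(dest), 1)]
        break
      }
      u <- u - rate_mig[pi]
    }
  }
  ape::read.tree(text = paste0(sub[[1]], ";"))
}

#' Drop infinite-sites mutations onto a genealogy
#'
#' Places `Poisson(mu * L * branch_years)` mutations per branch at
#' uniformly drawn, non-recurrent positions (each position mutates on at
#' most one branch) with a random ancestral base per site, and returns the
#' tip sequences.
#'
#' @param t a `phylo` genealogy with branch lengths in years.
#' @param mu substitution rate per site per year.
#' @param L sequence length in bp.
#' @return named character vector of A/C/G/T sequences, one per tip.
#' @export
drop_mutations <- function(t, mu, L) {
  bases <- c("A", "C", "G", "T")
  counts <- rpois(nrow(t$edge), mu * L * t$edge.length)
  S <- sum(counts)
  if (S > L)
    stop("more mutations (", S, ") than sites (", L,
         "): increase L or lower mu", call. = FALSE)
  anc <- sample(bases, L, replace = TRUE)
  pos <- if (S > 0) sample.int(L, S) else integer(0)
  derived <- vapply(pos, function(p) sample(setdiff(bases, anc[p]), 1),
                    character(1))
  edge_mut <- split(seq_len(S), rep(seq_len(nrow(t$edge)), counts))
  ntip <- ape::Ntip(t)
  root <- ntip + 1L
  seqs <- vector("list", ntip + t$Nnode)
  seqs[[root]] <- anc
  # preorder propagation
  ord <- ape::reorder.phylo(t, "postorder")
  for (k in rev(seq_len(nrow(ord$edge)))) {
    par <- ord$edge[k, 1]; child <- ord$edge[k, 2]
    eidx <- which(t$edge[, 1] == par & t$edge[, 2] == child)
    sq <- seqs[[par]]
    mu_idx <- edge_mut[[as.character(eidx)]]
    if (!is.null(mu_idx) && length(mu_idx)) {
      sq[pos[mu_idx]] <- derived[mu_idx]
    }
    seqs[[child]] <- sq
  }
  out <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                character(1))
  setNames(out, t$tip.label)
}

#' Collapse intra-individual copies to an IUPAC consensus
#'
#' Per site, the IUPAC symbol for the union of bases observed across an
#' individual's copies: differing copies yield 2ISP symbols (C + T -> Y),
#' identical copies leave the sequence unchanged, and a single copy is the
#' identity.
#'
#' @param copies character vector of equal-length A/C/G/T sequences.
#' @return a single consensus sequence string.
#' @export
collapse_to_2isp <- function(copies) {
  stopifnot(length(copies) >= 1)
  if (length(copies) == 1L) return(unname(copies))
  lens <- nchar(copies)
  if (length(unique(lens)) != 1L) stop("copies differ in length", call. = FALSE)
  mats <- do.call(rbind, strsplit(toupper(copies), "", fixed = TRUE))
  codes <- matrix(.BASE_BITS[mats], nrow = nrow(mats))
  if (anyNA(codes)) stop("copies must contain only A/C/G/T", call. = FALSE)
  merged <- Reduce(bitwOr, split(codes, row(codes)))
  paste(.CODE_SYMBOL[merged + 1L], collapse = "")
}

#' Simulate sampling localities clustered per catchment
#'
#' Draws coordinates uniformly within disjoint per-catchment bounding
#' boxes arranged west to east, enforcing a minimum great-circle spacing
#' between localities by rejection.
#'
#' @param cfg a [sim_config()].
#' @return data frame with sample_id, group, lat, lon.
#' @export
simulate_localities <- function(cfg) {
  lat0 <- -34.0; lat1 <- -32.9
  out <- NULL
  for (k in seq_len(cfg$K)) {
    lon0 <- 19 + (k - 1) * 1.8; lon1 <- lon0 + 1.5
    pts <- matrix(NA_real_, 0, 2)
    tries <- 0L
    while (nrow(pts) < cfg$n_per_catchment) {
      tries <- tries + 1L
      if (tries > 500L * cfg$n_per_catchment)
        stop("catchment box too small for requested spacing", call. = FALSE)
      cand <- c(runif(1, lon0, lon1), runif(1, lat0, lat1))
      ok <- !nrow(pts) || all(geosphere::distHaversine(
        cand, pts, r = 6371) >= cfg$min_spacing_km)
      if (ok) pts <- rbind(pts, cand)
    }
    out <- rbind(out, data.frame(
      sample_id = sprintf("%s_%02d", cfg$labels[k], seq_len(cfg$n_per_catchment)),
      group = cfg$labels[k], lat = pts[, 2], lon = pts[, 1]))
  }
  rownames(out) <- NULL
  out
}

#' Simulate current and LGM suitability grids with a pseudo-ensemble
#'
#' Current suitability is a sum of one Gaussian kernel per catchment plus
#' small noise; the LGM surface replaces each kernel by two smaller,
#' weaker sub-kernels, so the suitable range both contracts and fragments
#' within every catchment. Presence scores are sampled near kernel
#' centres and absence scores at random background cells; ensemble
#' members jitter kernel centres and widths and are binarised at their
#' own equal sensitivity-plus-specificity threshold.
#'
#' @param cfg a [sim_config()].
#' @return list with `current`, `lgm` (suitability grids), `masks` (per
#'   catchment label + logical matrix), `presence_scores`,
#'   `absence_scores`, `threshold`, `ensemble_current`, `ensemble_lgm`
#'   (lists of binary grids).
#' @export
simulate_sdm <- function(cfg) {
  nr <- cfg$grid_nrow; nc <- cfg$grid_ncol; K <- cfg$K
  band <- floor(nc / K)
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  kern <- function(r0, c0, sig, amp)
    amp * exp(-((rows - r0)^2 + (cols - c0)^2) / (2 * sig^2))
  centres <- lapply(seq_len(K), function(k)
    c(r = nr / 2, c = (k - 0.5) * band))
  sig_cur <- 0.30 * band
  surface <- function(jr = 0, jc = 0, sscale = 1, lgm = FALSE) {
    m <- matrix(0, nr, nc)
    for (k in seq_len(K)) {
      ct <- centres[[k]]
      if (!lgm) {
        m <- m + kern(ct["r"] + jr, ct["c"] + jc, sig_cur * sscale, 0.92)
      } else {
        off <- nr / 4.5
        m <- m + kern(ct["r"] - off + jr, ct["c"] + jc, sig_cur * 0.42 * sscale, 0.80)
        m <- m + kern(ct["r"] + off + jr, ct["c"] + jc, sig_cur * 0.42 * sscale, 0.80)
      }
    }
    pmin(pmax(m, 0), 1)
  }
  noise <- matrix(runif(nr * nc, -0.01, 0.01), nr, nc)
  cur <- suitability_grid(pmin(pmax(surface() + noise, 0), 1),
                          cellsize = cfg$grid_cellsize_km)
  lgm <- suitability_grid(pmin(pmax(surface(lgm = TRUE) + noise, 0), 1),
                          cellsize = cfg$grid_cellsize_km)
  masks <- lapply(seq_len(K), function(k) {
    m <- matrix(FALSE, nr, nc)
    hi <- if (k == K) nc else k * band
    m[, ((k - 1) * band + 1):hi] <- TRUE
    list(label = cfg$labels[k], mask = m)
  })
  pres_cells <- do.call(rbind, lapply(centres, function(ct) {
    cbind(pmin(pmax(round(ct["r"] + runif(15, -sig_cur, sig_cur)), 1), nr),
          pmin(pmax(round(ct["c"] + runif(15, -sig_cur, sig_cur)), 1), nc))
  }))
  abs_cells <- cbind(sample.int(nr, 45, replace = TRUE),
                     sample.int(nc, 45, replace = TRUE))
  presence_scores <- cur$values[pres_cells]
  absence_scores <- cur$values[abs_cells]
  threshold <- equal_ss_threshold(presence_scores, absence_scores)
  member <- function(lgm_flag) {
    jr <- runif(1, -2, 2); jc <- runif(1, -2, 2); ss <- runif(1, 0.85, 1.15)
    s <- surface(jr, jc, ss, lgm = lgm_flag)
    tt <- equal_ss_threshold(s[pres_cells], s[abs_cells])
    binary_grid(s >= tt, cellsize = cfg$grid_cellsize_km)
  }
  ens_cur <- lapply(seq_len(cfg$n_models), function(i) member(FALSE))
  ens_lgm <- lapply(seq_len(cfg$n_models), function(i) member(TRUE))
  list(current = cur, lgm = lgm, masks = masks,
       presence_scores = presence_scores, absence_scores = absence_scores,
       threshold = threshold,
       ensemble_current = ens_cur, ensemble_lgm = ens_lgm)
}

#' Simulate a full catchment-structured dataset
#'
#' Runs every simulator component under one seed: localities, per-locus
#' genealogies, infinite-sites mutations, 2ISP collapse of multi-copy
#' loci (with optional contact-zone copy swaps), and the paired
#' current/LGM suitability grids.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `sim_output`: list with `config`, `table`
#'   (a `sample_table`), `alignments` (named list of `twoisp_alignment`),
#'   `genealogies` (named list of `phylo`, tips may carry copy
#'   suffixes), and `sdm` (see [simulate_sdm()]).
#' @export
simulate_dataset <- function(cfg) {
  set.seed(cfg$seed)
  loc <- simulate_localities(cfg)
  table <- as_sample_table(data.frame(loc, role = "ingroup"))
  alignments <- list()
  genealogies <- list()
  for (lc in cfg$loci) {
    tr <- simulate_genealogy(cfg, copies = lc$copies)
    seqs <- drop_mutations(tr, lc$mu, lc$L)
    if (lc$copies > 1) {
      ind <- sub("\\.[0-9]+$", "", names(seqs))
      seqs <- .apply_contact_swaps(seqs, ind, cfg)
      cons <- vapply(split(seqs, ind)[unique(ind)], collapse_to_2isp,
                     character(1))
    } else {
      cons <- seqs
    }
    cons <- cons[.sample_ids(cfg)]
    alignments[[lc$name]] <- twoisp_alignment(cons, locus = lc$name)
    genealogies[[lc$name]] <- tr
  }
  structure(list(config = cfg, table = table, alignments = alignments,
                 genealogies = genealogies, sdm = simulate_sdm(cfg)),
            class = "sim_output")
}

# contact-zone emulation: with probability contact_fraction per internal
# boundary, the first individual of the eastern catchment gets one copy
# swapped for a random copy from the western neighbour
.apply_contact_swaps <- function(seqs, ind, cfg) {
  if (cfg$contact_fraction <= 0 || cfg$K < 2) return(seqs)
  for (k in seq_len(cfg$K - 1)) {
    if (runif(1) >= cfg$contact_fraction) next
    east_id <- sprintf("%s_%02d", cfg$labels[k + 1], 1L)
    west_pool <- which(startsWith(ind, cfg$labels[k]))
    tgt <- which(ind == east_id)[1]
    seqs[tgt] <- seqs[sample(west_pool, 1)]
  }
  seqs
}

#' Write a simulated dataset to a fixture directory
#'
#' Emits exactly the formats the pipeline reads: one FASTA per locus, the
#' sample table TSV, true genealogies as Newick, current/LGM/mask grids
#' as ESRI ASCII, presence/absence scores, and a manifest JSON carrying
#' the configuration and seed. Re-running with the same seed is
#' byte-identical.
#'
#' @param sim a `sim_output` from [simulate_dataset()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_fixture_set <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  for (nm in names(sim$alignments))
    write_alignment(sim$alignments[[nm]], file.path(out_dir, paste0(nm, ".fasta")))
  write.table(as.data.frame(sim$table)[, c("sample_id", "group", "lat", "lon", "role")],
              file.path(out_dir, "samples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(sim$genealogies))
    ape::write.tree(sim$genealogies[[nm]],
                    file.path(out_dir, paste0(nm, "_true.nwk")))
  write_ascii_grid(sim$sdm$current, file.path(out_dir, "suitability_current.asc"))
  write_ascii_grid(sim$sdm$lgm, file.path(out_dir, "suitability_lgm.asc"))
  for (mk in sim$sdm$masks)
    write_ascii_grid(binary_grid(mk$mask, sim$sdm$current$cellsize),
                     file.path(out_dir, paste0("mask_", mk$label, ".asc")))
  write.table(data.frame(kind = c(rep("presence", length(sim$sdm$presence_scores)),
                                  rep("absence", length(sim$sdm$absence_scores))),
                         score = c(sim$sdm$presence_scores, sim$sdm$absence_scores)),
              file.path(out_dir, "sdm_scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  manifest <- list(seed = cfg$seed, K = cfg$K,
                   n_per_catchment = cfg$n_per_catchment,
                   split_times = cfg$split_times, Ne = cfg$Ne,
                   generation_time = cfg$generation_time,
                   migration_rate = cfg$migration_rate,
                   contact_fraction = cfg$contact_fraction,
                   loci = cfg$loci, labels = cfg$labels,
                   grid = list(nrow = cfg$grid_nrow, ncol = cfg$grid_ncol,
                               cellsize_km = cfg$grid_cellsize_km),
                   n_models = cfg$n_models)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
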