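#' Assemble a pipeline run configuration
#'
#' Collects every input and constant of the full analysis: per-locus FASTA
#' paths and distance methods (plain p for cpDNA, polymorphism p for
#' nuclear loci), the sample table, reassignment/exclusion rules, pooled
#' group definitions, bootstrap and permutation effort, the gsi sorting
#' threshold, the bracketing substitution rates, optional SDM grid paths,
#' and the seed driving every stochastic stage.
#'
#' @param loci named character vector of FASTA paths (names = locus
#'   labels).
#' @param methods named character vector, locus -> `"p"` or `"poly_p"`
#'   (default `"poly_p"` for every locus).
#' @param sample_table path to the sample TSV.
#' @param rules a [rule_set()].
#' @param pooled named list of pooled-group definitions.
#' @param outgroup character vector of outgroup sample ids (used for
#'   rooting; may be empty).
#' @param dating_locus locus used for the chronogram and time scaling
#'   (default the first locus).
#' @param n_boot bootstrap replicates (default 1000).
#' @param n_perm Mantel permutations (default 10000).
#' @param gsi_threshold ensemble-gsi sorting threshold (default 0.6).
#' @param rate_slow,rate_fast bracketing substitution rates
#'   (defaults 1.0e-9 and 31e-9 substitutions/site/year).
#' @param sdm list with optional paths: `current`, `lgm` (ASCII grids),
#'   `masks` (named vector of mask grid paths), `scores` (TSV with
#'   columns kind, score), or NULL to skip the SDM stage.
#' @param seed integer seed (mandatory).
#' @param out_dir output directory.
#' @return an object of class `run_config`.
#' @export
run_config <- function(loci, sample_table, out_dir, seed,
                       methods = NULL, rules = rule_set(),
                       pooled = list(), outgroup = character(0),
                       dating_locus = names(loci)[1],
                       n_boot = 1000, n_perm = 10000, gsi_threshold = 0.6,
                       rate_slow = 1.0e-9, rate_fast = 31e-9,
                       sdm = NULL) {
  stopifnot(!is.null(names(loci)), length(seed) == 1L)
  for (p in c(loci, sample_table)) if (!file.exists(p))
    stop("configuration error: missing input file: ", p, call. = FALSE)
  if (is.null(methods)) methods <- setNames(rep("poly_p", length(loci)), names(loci))
  structure(list(loci = loci, methods = methods, sample_table = sample_table,
                 rules = rules, pooled = pooled, outgroup = outgroup,
                 dating_locus = dating_locus, n_boot = n_boot,
                 n_perm = n_perm, gsi_threshold = gsi_threshold,
                 rate_slow = rate_slow, rate_fast = rate_fast,
                 sdm = sdm, seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of [run_config()]
#' (`rules` given as `reassignments` / `exclusions` lists). Relative paths
#' are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  rules <- rule_set(
    reassignments = if (!is.null(y$rules$reassignments))
      do.call(rbind, lapply(y$rules$reassignments, as.data.frame)),
    exclusions = if (!is.null(y$rules$exclusions))
      do.call(rbind, lapply(y$rules$exclusions, as.data.frame)))
  sdm <- if (!is.null(y$sdm)) list(
    current = resolve(y$sdm$current), lgm = resolve(y$sdm$lgm),
    masks = setNames(resolve(unlist(y$sdm$masks)), names(y$sdm$masks)),
    scores = resolve(y$sdm$scores))
  run_config(
    loci = setNames(resolve(unlist(y$loci)), names(y$loci)),
    methods = if (!is.null(y$methods)) unlist(y$methods),
    sample_table = resolve(y$sample_table),
    rules = rules,
    pooled = y$pooled %||% list(),
    outgroup = y$outgroup %||% character(0),
    dating_locus = y$dating_locus %||% names(y$loci)[1],
    n_boot = y$n_boot %||% 1000, n_perm = y$n_perm %||% 10000,
    gsi_threshold = y$gsi_threshold %||% 0.6,
    rate_slow = y$rate_slow %||% 1.0e-9, rate_fast = y$rate_fast %||% 31e-9,
    sdm = sdm, seed = y$seed, out_dir = resolve(y$out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes the stages in order — read alignments, apply sample rules,
#' distance matrices, diversity/Mantel summary, bootstrap ensembles and
#' ensemble gsi per group, UPGMA chronogram with rate-bracketed time
#' scaling, and (when grids are configured) SDM thresholding, ensemble
#' stacking and per-catchment patch metrics — writing TSV reports, Newick
#' trees and a machine-readable manifest into the output directory. The
#' manifest is written even when a stage fails, recording the failed
#' stage; reruns under the same seed are identical.
#'
#' @param cfg a [run_config()].
#' @return the output directory, invisibly.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(cfg$out_dir, "trees"), showWarnings = FALSE)
  stages <- character(0)
  manifest <- list(seed = cfg$seed, version = as.character(utils::packageVersion("phylocatch")),
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(status = "ok", ...)
    stages <<- c(stages, stage)
  }
  finish <- function() {
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      manifest$stages[[stage]] <<- list(status = "failed",
                                        error = conditionMessage(e))
      finish()
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  loci <- run_stage("read", {
    out <- lapply(names(cfg$loci), function(nm)
      code_indels(read_alignment(cfg$loci[[nm]], locus = nm)))
    names(out) <- names(cfg$loci)
    out
  })
  note("read", loci = names(loci),
       lengths = vapply(loci, `[[`, numeric(1), "length"))

  table <- run_stage("rules", {
    apply_sample_rules(read_sample_table(cfg$sample_table), cfg$rules)
  })
  note("rules", n_samples = nrow(table), n_excluded = sum(table$excluded))

  run_stage("summary", {
    summ <- diversity_summary(loci, table, pooled = cfg$pooled,
                              methods = cfg$methods, n_perm = cfg$n_perm,
                              seed = cfg$seed)
    write.table(summ, file.path(cfg$out_dir, "summary_table.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    mant <- summ[, c("locus", "group", "n", "mt_r", "mt_p")]
    mant$stars <- .p_stars(mant$mt_p)
    write.table(mant, file.path(cfg$out_dir, "mantel_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    summ
  })
  note("summary")

  active <- .active_samples(table)
  groups <- c(setNames(lapply(unique(table$group[table$sample_id %in% active]),
                              function(g) table$sample_id[table$group == g &
                                                          table$sample_id %in% active]),
                       unique(table$group[table$sample_id %in% active])),
              lapply(cfg$pooled, function(parts)
                table$sample_id[table$group %in% parts &
                                table$sample_id %in% active]))
  gsi_rows <- run_stage("gsi", {
    rows <- list()
    for (nm in names(loci)) {
      a <- loci[[nm]]
      ids <- intersect(c(active, cfg$outgroup), a$ids)
      if (length(ids) < 3L) next
      ens <- bootstrap_ensemble(a, n_reps = cfg$n_boot, seed = cfg$seed,
                                method = cfg$methods[[nm]], samples = ids,
                                outgroup = intersect(cfg$outgroup, ids))
      ape::write.tree(ens, file.path(cfg$out_dir, "trees",
                                     paste0(nm, "_bootstrap.nwk")))
      for (grp in names(groups)) {
        members <- intersect(groups[[grp]], a$ids)
        if (length(members) < 2L || length(members) >= length(ids) - 1L) next
        gr <- ensemble_gsi(ens, members, threshold = cfg$gsi_threshold)
        rows[[length(rows) + 1L]] <- data.frame(
          locus = nm, group = grp, mean = gr$mean, sd = gr$sd,
          passes = gr$passes_threshold)
      }
    }
    rows <- do.call(rbind, rows)
    write.table(rows, file.path(cfg$out_dir, "gsi_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    rows
  })
  note("gsi", n_rows = nrow(gsi_rows))

  run_stage("dating", {
    a <- loci[[cfg$dating_locus]]
    ids <- intersect(active, a$ids)
    d <- genetic_distance_matrix(a, method = cfg$methods[[cfg$dating_locus]],
                                 samples = ids)
    chrono <- upgma_chronogram(d)
    scaled <- scale_to_time(chrono, rate_slow = cfg$rate_slow,
                            rate_fast = cfg$rate_fast)
    ape::write.tree(chrono, file.path(cfg$out_dir, "trees", "chronogram.nwk"))
    ape::write.tree(scaled$slow, file.path(cfg$out_dir, "trees", "chronogram_slow_yr.nwk"))
    ape::write.tree(scaled$fast, file.path(cfg$out_dir, "trees", "chronogram_fast_yr.nwk"))
    write.table(scaled$ages, file.path(cfg$out_dir, "dating_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  })
  note("dating", locus = cfg$dating_locus)

  if (!is.null(cfg$sdm)) {
    run_stage("sdm", {
      cur <- read_ascii_grid(cfg$sdm$current)
      lgm <- read_ascii_grid(cfg$sdm$lgm)
      scores <- read.delim(cfg$sdm$scores)
      thr <- equal_ss_threshold(scores$score[scores$kind == "presence"],
                                scores$score[scores$kind == "absence"])
      bc <- binarize(cur, thr); bl <- binarize(lgm, thr)
      rows <- list()
      for (nm in names(cfg$sdm$masks)) {
        mk <- read_ascii_grid(cfg$sdm$masks[[nm]])$values > 0.5
        rows[[length(rows) + 1L]] <- patch_metrics(bc, mk, label = nm,
                                                   scenario = "current")
        rows[[length(rows) + 1L]] <- patch_metrics(bl, mk, label = nm,
                                                   scenario = "LGM")
      }
      rep <- do.call(rbind, rows)
      chg <- scenario_change(rep[rep$scenario == "current", ],
                             rep[rep$scenario == "LGM", ])
      out <- merge(rep, chg, by = "catchment", all.x = TRUE)
      write.table(out, file.path(cfg$out_dir, "sdm_report.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      out
    })
    note("sdm", threshold = "equal_sens_spec")
  }

  finish()
  invisible(cfg$out_dir)
}

.p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}
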