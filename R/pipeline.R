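#' Allometry stage over several taxa
#'
#' Fits [allometry()] to each supplied specimen table (or to tables
#' generated from synthetic configurations) and assembles a wide
#' coefficient table: one row per taxon, with an `AC`, `CI` and `A`
#' (class) column triplet per dimension.
#'
#' @param tables Named list whose elements are [specimen_table]s or
#'   [synthetic_taxon_config()]s (the latter are generated first).
#' @param boot,seed,alpha Passed to [allometry()].
#' @param out_dir Optional directory; when given, the wide table is written
#'   to `allometry.csv` there.
#' @return List with `fits` (named list of `allometry` objects) and
#'   `table` (the wide data frame).
#' @export
run_allometry <- function(tables, boot = 1000L, seed = 1L, alpha = 0.05,
                          out_dir = NULL) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  if (is.null(names(tables)))
    names(tables) <- vapply(tables, function(t)
      if (inherits(t, "synthetic_taxon_config")) t$taxon else taxon_name(t), "")
  fits <- lapply(names(tables), function(nm) {
    t <- tables[[nm]]
    combine <- FALSE
    if (inherits(t, "synthetic_taxon_config")) {
      combine <- t$combine_wp34
      t <- generate_taxon(t)
    }
    tryCatch(allometry(t, combine_wp34 = combine, boot = boot, seed = seed,
                       alpha = alpha),
             error = function(e)
               stop("allometry failed for taxon '", nm, "': ",
                    conditionMessage(e)))
  })
  names(fits) <- names(tables)
  all_dims <- unique(unlist(lapply(fits, function(f) f$table$dimension)))
  rows <- lapply(fits, function(f) {
    out <- list(taxon = f$taxon)
    for (d in all_dims) {
      i <- match(d, f$table$dimension)
      out[[paste0(d, "_AC")]] <- if (is.na(i)) NA else f$table$ac[i]
      out[[paste0(d, "_CI")]] <- if (is.na(i)) NA else f$table$bound[i]
      out[[paste0(d, "_A")]] <- if (is.na(i)) NA else f$table$class[i]
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  wide <- do.call(rbind, rows)
  rownames(wide) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(wide, file.path(out_dir, "allometry.csv"),
                     row.names = FALSE)
  }
  list(fits = fits, table = wide)
}

# Seed specimen of a table: the complete specimen with the largest
# computable wingspan (for anchored synthetic tables, the upper anchor).
pick_seed <- function(tab, combine_wp34 = FALSE) {
  ws <- table_wingspans(tab)
  if (all(is.na(ws))) stop("no complete specimen to seed extrapolation")
  i <- which.max(ws)
  v <- unlist(tab[i, setdiff(names(tab), "specimen_id")])
  v <- v[!is.na(v)]
  if (combine_wp34) {
    if (!all(c("wp3", "wp4") %in% names(v)))
      stop("seed specimen lacks wp3/wp4 for combination")
    v <- c(v[setdiff(names(v), c("wp3", "wp4"))],
           wp34 = unname(v[["wp3"]] + v[["wp4"]]))
  }
  seed_specimen(v, specimen_id = tab$specimen_id[i])
}

#' Full ontogenetic flight-performance pipeline
#'
#' Runs every stage for a set of taxa: allometry estimation, growth
#' extrapolation over a wingspan grid, planform reconstruction under one or
#' two postures, flight-performance evaluation under one or two body-mass
#' scaling models, and pair-wise permutation comparison of the flight
#' efficiency and glide-ratio series.  With a single taxon the permutation
#' stage is skipped with a warning.
#'
#' @param tables As in [run_allometry()]; synthetic configurations also
#'   provide the mass-model group and the WP3--4 combination flag.
#' @param postures Character subset of `c("taxon_specific", "neutral")`.
#' @param mass_methods Character subset of `c("witton", "henderson")`.
#' @param grid Wingspan grid in metres.
#' @param boot,seed Bootstrap settings for the allometry stage; `seed` also
#'   seeds the permutation stage.
#' @param n_perm Monte-Carlo permutation sample size.
#' @param out_dir Optional output directory: writes `allometry.csv`,
#'   `performance.csv`, per-index/posture/mass p-value CSVs, one SVG
#'   planform per taxon and posture at the grid extremes, and a
#'   `manifest.csv` of outputs with MD5 hashes.
#' @return List with `allometry`, `series` (growth series per taxon),
#'   `performance` (long data frame over taxa, postures, mass methods),
#'   `comparisons` (nested list of pairwise test results), `groups`.
#' @export
run_full <- function(tables = preset_library(),
                     postures = c("taxon_specific", "neutral"),
                     mass_methods = c("witton", "henderson"),
                     grid = default_wingspan_grid(),
                     boot = 1000L, seed = 1L, n_perm = 1e5L,
                     out_dir = NULL) {
  postures <- match.arg(postures, several.ok = TRUE)
  mass_methods <- match.arg(mass_methods,
                            c("witton", "henderson"), several.ok = TRUE)
  groups <- lapply(tables, function(t)
    if (inherits(t, "synthetic_taxon_config")) t$group else "pterodactyloid")
  combine <- lapply(tables, function(t)
    if (inherits(t, "synthetic_taxon_config")) t$combine_wp34 else FALSE)
  allom <- run_allometry(tables, boot = boot, seed = seed, out_dir = out_dir)
  taxa <- names(allom$fits)
  names(groups) <- names(combine) <- taxa

  mats <- lapply(taxa, function(nm) {
    t <- tables[[nm]]
    if (inherits(t, "synthetic_taxon_config")) generate_taxon(t) else t
  })
  names(mats) <- taxa
  series <- lapply(taxa, function(nm) {
    sd <- pick_seed(mats[[nm]], combine_wp34 = combine[[nm]])
    predict(allom$fits[[nm]], sd, grid = grid)
  })
  names(series) <- taxa

  perf <- list()
  svg_files <- character()
  for (nm in taxa) {
    for (post in postures) {
      po <- if (post == "neutral")
              posture_preset("neutral", combine_wp34 = combine[[nm]])
            else posture_preset(nm, combine_wp34 = combine[[nm]])
      for (mm in mass_methods) {
        mdl <- mass_model(mm, groups[[nm]])
        perf[[paste(nm, post, mm, sep = ".")]] <-
          flight_performance_series(series[[nm]], po, mdl)
      }
      if (!is.null(out_dir)) {
        for (z in range(series[[nm]]$wingspan_m)) {
          pf <- build_planform(series[[nm]], po, z)
          f <- file.path(out_dir, sprintf("planform_%s_%s_%.1fm.svg",
                                          nm, post, z))
          write_planform_svg(pf, f)
          svg_files <- c(svg_files, f)
        }
      }
    }
  }
  perf_long <- do.call(rbind, perf)
  rownames(perf_long) <- NULL

  comparisons <- list()
  if (length(taxa) < 2L) {
    warning("only one taxon supplied: permutation comparison skipped")
  } else {
    for (post in postures) {
      for (mm in mass_methods) {
        key <- paste(post, mm, sep = ".")
        sl <- perf[paste(taxa, post, mm, sep = ".")]
        names(sl) <- taxa
        comparisons[[key]] <- list(
          cot_inv = pairwise_performance_tests(sl, "cot_inv",
                                               n_perm = n_perm, seed = seed),
          glide_ratio = pairwise_performance_tests(sl, "glide_ratio",
                                                   n_perm = n_perm,
                                                   seed = seed))
      }
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(perf_long, file.path(out_dir, "performance.csv"),
                     row.names = FALSE)
    for (key in names(comparisons)) {
      for (idx in names(comparisons[[key]])) {
        utils::write.csv(comparisons[[key]][[idx]]$p_values,
                         file.path(out_dir, sprintf("pvalues_%s_%s.csv",
                                                    idx, key)))
      }
    }
    files <- c(file.path(out_dir, c("allometry.csv", "performance.csv")),
               list.files(out_dir, pattern = "^pvalues_", full.names = TRUE),
               svg_files)
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)),
                           stringsAsFactors = FALSE)
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(allometry = allom, series = series, performance = perf_long,
       comparisons = comparisons, groups = groups)
}
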