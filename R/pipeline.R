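## Orchestration: config validation, stage running, group statistics and the
## compact letter display used to annotate per-population distributions.

#' Compact letter display from a pairwise significance matrix
#'
#' Insert-and-absorb algorithm: groups that are NOT significantly different
#' share at least one letter; significantly different groups share none.
#'
#' @param sig symmetric logical matrix (TRUE = significantly different),
#'   diagonal FALSE, dimnames = group names.
#' @return named character vector of letter strings, one per group.
#' @export
assign_group_letters <- function(sig) {
  if (!is.matrix(sig) || nrow(sig) != ncol(sig))
    stop("sig must be a square matrix")
  if (!isTRUE(all(sig == t(sig)))) stop("sig matrix must be symmetric")
  if (any(diag(sig))) stop("sig matrix diagonal must be FALSE")
  g <- rownames(sig) %||% as.character(seq_len(nrow(sig)))
  rownames(sig) <- colnames(sig) <- g
  cols <- list(g)
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  for (pi in seq_len(nrow(pairs))) {
    a <- g[pairs[pi, 1L]]; b <- g[pairs[pi, 2L]]
    newcols <- list()
    for (col in cols) {
      if (a %in% col && b %in% col) {
        newcols <- c(newcols, list(setdiff(col, a)), list(setdiff(col, b)))
      } else newcols <- c(newcols, list(col))
    }
    ## absorb: drop columns that are subsets of another column
    keep <- rep(TRUE, length(newcols))
    for (i in seq_along(newcols)) for (j in seq_along(newcols)) {
      if (i != j && keep[i] && keep[j] &&
          all(newcols[[i]] %in% newcols[[j]]) &&
          !(all(newcols[[j]] %in% newcols[[i]]) && i < j))
        keep[i] <- FALSE
    }
    cols <- newcols[keep]
  }
  cols <- cols[order(vapply(cols, function(cl) min(match(cl, g)), 1L))]
  letters_used <- c(letters, paste0(rep(letters, each = 26L), letters))
  out <- stats::setNames(rep("", length(g)), g)
  for (ci in seq_along(cols)) {
    for (grp in cols[[ci]])
      out[grp] <- paste0(out[grp], letters_used[ci])
  }
  out
}

#' Kruskal-Wallis test with pairwise Wilcoxon post hoc and letters
#'
#' Kruskal-Wallis H with tie correction and df = k - 1; all pairwise
#' two-sided rank-sum tests adjusted with Holm (configurable); compact
#' letters at `alpha`. NAs are dropped per group before testing.
#'
#' @param values named list: one numeric vector of window statistics per
#'   population.
#' @param alpha significance level for the letter display.
#' @param p_adjust multiple-testing adjustment method (see
#'   [stats::p.adjust()]).
#' @param statistic optional label carried through to the output.
#' @return list with `statistic`, `H`, `df`, `p`, `pairwise` (data.table
#'   group_a, group_b, p, p_adj) and `letters`.
#' @export
compare_groups <- function(values, alpha = 0.05, p_adjust = "holm",
                           statistic = NA_character_) {
  if (length(values) < 2L) stop("need >= 2 groups")
  if (is.null(names(values))) names(values) <- paste0("g", seq_along(values))
  values <- lapply(values, function(v) v[!is.na(v)])
  bad <- names(values)[vapply(values, length, 1L) < 2L]
  if (length(bad))
    stop(sprintf("group(s) with < 2 non-NA values: %s",
                 paste(bad, collapse = ", ")))
  kw <- stats::kruskal.test(values)
  nm <- names(values)
  pr <- utils::combn(nm, 2L)
  pvals <- apply(pr, 2L, function(ab)
    stats::wilcox.test(values[[ab[1L]]], values[[ab[2L]]],
                       alternative = "two.sided", exact = FALSE)$p.value)
  padj <- stats::p.adjust(pvals, method = p_adjust)
  sig <- matrix(FALSE, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_len(ncol(pr))) {
    s <- padj[i] < alpha
    sig[pr[1L, i], pr[2L, i]] <- s
    sig[pr[2L, i], pr[1L, i]] <- s
  }
  list(statistic = statistic,
       H = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value,
       pairwise = data.table::data.table(group_a = pr[1L, ],
                                         group_b = pr[2L, ],
                                         p = pvals, p_adj = padj),
       letters = assign_group_letters(sig))
}

## ------------------------------------------------------------------ config --

#' Validate a run configuration
#'
#' @param config a nested list (typically read from a JSON file).
#' @return the config with defaults filled in; errors name the offending
#'   field.
#' @export
validate_config <- function(config) {
  req_pop_fields <- c("name", "pool_size", "max_coverage")
  if (is.null(config$populations) || !length(config$populations))
    stop("config field 'populations' is missing or empty")
  pops <- config$populations
  if (is.data.frame(pops))
    pops <- split(pops, seq_len(nrow(pops)))
  for (i in seq_along(pops)) {
    p <- as.list(pops[[i]])
    for (f in req_pop_fields)
      if (is.null(p[[f]]) || is.na(p[[f]]))
        stop(sprintf("config field 'populations[%d].%s' is missing", i, f))
    p$column <- p$column %||% i
    p$min_count <- p$min_count %||% 2L
    p$min_coverage <- p$min_coverage %||% 4L
    pops[[i]] <- p
  }
  config$populations <- pops
  if (is.null(config$sync) && is.null(config$simulate))
    stop("config needs either 'sync' (input path) or 'simulate' (generator)")
  config$seed <- config$seed %||% 1L
  config$window_size <- config$window_size %||% 100000L
  config$min_covered_fraction <- config$min_covered_fraction %||% 0.6
  config$alpha <- config$alpha %||% 0.05
  config$p_adjust <- config$p_adjust %||% "holm"
  config$dxy_snps_only <- config$dxy_snps_only %||% FALSE
  config
}

#' Run the configured pipeline stages
#'
#' Executes input acquisition (sync file or the synthetic generator),
#' per-population window diversity, pairwise differentiation, group
#' comparisons and (when configured) the TE stages, writing tab-separated
#' tables and a JSON manifest (parameters, seeds, input and output
#' checksums) to `output_dir`. Identical config + inputs + seeds give
#' identical output checksums.
#'
#' @param config run configuration (list or path to a JSON file).
#' @param output_dir report directory (created if needed).
#' @param stages character vector of stages to run, or `"all"`. Stages:
#'   simulate/input, diversity, differentiation, compare, te-call,
#'   te-spectrum, landscape, composition, telomere.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, output_dir, stages = "all") {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  config <- validate_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  want <- function(s) identical(stages, "all") || s %in% stages
  manifest <- list(package = "poolscape",
                   version = as.character(utils::packageVersion("poolscape")),
                   config = config, inputs = list(), outputs = list())
  window <- window_spec(size = as.integer(config$window_size),
                        min_covered_fraction = config$min_covered_fraction)
  pools <- lapply(config$populations, function(p)
    pool_spec(p$name, p$pool_size, p$min_count, p$min_coverage,
              p$max_coverage))
  cols <- vapply(config$populations, function(p) as.integer(p$column), 1L)
  names(pools) <- vapply(pools, `[[`, "", "name")

  ## --- input ---------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sm <- config$simulate
    dem <- do.call(demography_model, as.list(sm$demography %||% list()))
    sqp <- seq_params(L = sm$L %||% 500000L,
                      mean_coverage = sm$mean_coverage %||% 60,
                      error_rate = sm$error_rate %||% 0.001,
                      pool_sizes = stats::setNames(
                        vapply(config$populations, function(p)
                          as.integer(p$pool_size), 1L),
                        names(pools)))
    sim <- simulate_pool_seq(dem, sqp, rng_seed = config$seed)
    sites <- sim$sites
    write_truth(sim$truth, file.path(output_dir, "truth.json"))
    sync_path <- file.path(output_dir, "input.sync")
    write_sync(sites, sync_path)
    manifest$inputs$sync <- unname(tools::md5sum(sync_path))
  } else {
    sites <- read_sync(config$sync)
    manifest$inputs$sync <- unname(tools::md5sum(config$sync))
  }
  mask <- NULL
  if (!is.null(config$mpileup)) {
    mp <- read_mpileup(config$mpileup, n_pools = length(pools))
    mask <- identify_indel_regions(mp, min_count = config$indel_min_count %||% 2L,
                                   flank = config$indel_flank %||% 5L)
    sites <- apply_mask(sites, mask)
    manifest$inputs$mpileup <- unname(tools::md5sum(config$mpileup))
  }

  outputs <- character(0)
  win_tables <- NULL
  if (want("diversity")) {
    win_tables <- data.table::rbindlist(lapply(seq_along(pools), function(i)
      cbind(population = pools[[i]]$name,
            window_stats(sites, pools[[i]], window, pool_index = cols[i]))))
    p <- file.path(output_dir, "windows.tsv")
    data.table::fwrite(win_tables, p, sep = "\t")
    outputs <- c(outputs, p)
  }
  pair_tables <- NULL
  if (want("differentiation") && length(pools) >= 2L) {
    prs <- utils::combn(seq_along(pools), 2L)
    pair_tables <- data.table::rbindlist(lapply(seq_len(ncol(prs)), function(k) {
      i <- prs[1L, k]; j <- prs[2L, k]
      fst <- window_fst(sites, pools[c(i, j)], window,
                        pool_indices = cols[c(i, j)])
      dxy <- window_dxy(sites, pools[c(i, j)], window,
                        pool_indices = cols[c(i, j)],
                        rng_seed = child_seed(config$seed, "dxy"),
                        snps_only = config$dxy_snps_only)
      merge(fst, dxy[, .(chrom, start, pop_a, pop_b, dxy)],
            by = c("chrom", "start", "pop_a", "pop_b"))
    }), fill = TRUE)
    data.table::setorder(pair_tables, pop_a, pop_b, chrom, start)
    p <- file.path(output_dir, "pairs.tsv")
    data.table::fwrite(pair_tables, p, sep = "\t")
    outputs <- c(outputs, p)
  }
  if (want("compare") && !is.null(win_tables)) {
    cmp <- list()
    for (stat in c("pi", "tajima_d", "delta_theta")) {
      vals <- split(win_tables[[stat]], win_tables$population)
      ok <- vapply(vals, function(v) sum(!is.na(v)) >= 2L, TRUE)
      if (sum(ok) >= 2L)
        cmp[[stat]] <- compare_groups(vals[ok], alpha = config$alpha,
                                      p_adjust = config$p_adjust,
                                      statistic = stat)
    }
    if (!is.null(pair_tables)) {
      for (stat in c("fst", "dxy")) {
        pt <- pair_tables
        pt[, pair := paste(pop_a, pop_b, sep = ":")]
        vals <- split(pt[[stat]], pt$pair)
        ok <- vapply(vals, function(v) sum(!is.na(v)) >= 2L, TRUE)
        if (sum(ok) >= 2L)
          cmp[[stat]] <- compare_groups(vals[ok], alpha = config$alpha,
                                        p_adjust = config$p_adjust,
                                        statistic = stat)
      }
    }
    if (length(cmp)) {
      tab <- data.table::rbindlist(lapply(cmp, function(x)
        data.table::data.table(statistic = x$statistic, H = x$H, df = x$df,
                               p = x$p,
                               letters = paste(names(x$letters),
                                               x$letters, sep = "=",
                                               collapse = ";"))))
      p <- file.path(output_dir, "group_comparisons.tsv")
      data.table::fwrite(tab, p, sep = "\t")
      outputs <- c(outputs, p)
    }
  }

  ## --- TE stages -----------------------------------------------------------
  if (want("te-call") && !is.null(config$te)) {
    hier <- if (!is.null(config$te$hierarchy))
      read_te_hierarchy(config$te$hierarchy) else NULL
    sp <- do.call(signature_params, as.list(config$te$params %||% list()))
    calls <- list()
    for (popn in names(config$te$evidence)) {
      ev <- data.table::fread(config$te$evidence[[popn]], sep = "\t")
      calls[[popn]] <- detect_te_insertions(
        ev, sp, rng_seed = child_seed(config$seed, paste0("te", popn)),
        hierarchy = hier)
    }
    all_ins <- data.table::rbindlist(calls, idcol = "population")
    p <- file.path(output_dir, "insertions.tsv")
    data.table::fwrite(all_ins, p, sep = "\t")
    outputs <- c(outputs, p)
    uniq <- unique_insertions(calls,
                              tolerance = config$te$tolerance %||% 25L)
    if (want("te-spectrum")) {
      spec_tab <- data.table::rbindlist(lapply(names(uniq), function(popn) {
        fs <- frequency_spectrum(uniq[[popn]])
        data.table::data.table(population = popn,
                               n_unique = nrow(uniq[[popn]]),
                               low_fraction = fs$low_fraction,
                               high_fraction = fs$high_fraction,
                               fixed_fraction = fs$fixed_fraction)
      }))
      p <- file.path(output_dir, "spectra.tsv")
      data.table::fwrite(spec_tab, p, sep = "\t")
      outputs <- c(outputs, p)
    }
  }
  if (want("landscape") && !is.null(config$landscape)) {
    ls <- config$landscape
    reads <- Biostrings::readDNAStringSet(ls$reads)
    lib <- Biostrings::readDNAStringSet(ls$library)
    hier <- read_te_hierarchy(ls$hierarchy)
    land <- repeat_landscape(reads, lib, hier,
                             sample_coverage = ls$sample_coverage %||% 0.1,
                             genome_size = ls$genome_size,
                             rng_seed = child_seed(config$seed, "land"))
    p <- file.path(output_dir, "landscape.tsv")
    data.table::fwrite(land, p, sep = "\t")
    outputs <- c(outputs, p)
  }
  if (want("composition") && !is.null(config$composition)) {
    fx <- data.table::fread(config$composition$features, sep = "\t")
    gl <- unlist(config$composition$genome_lengths)
    comp <- window_composition(fx, window, gl)
    p <- file.path(output_dir, "composition.tsv")
    data.table::fwrite(comp, p, sep = "\t")
    outputs <- c(outputs, p)
  }
  if (want("telomere") && !is.null(config$telomere)) {
    gen <- Biostrings::readDNAStringSet(config$telomere$genome)
    ts <- telomere_scan(gen,
                        window = config$telomere$window %||% 10000L)
    p <- file.path(output_dir, "telomere.tsv")
    data.table::fwrite(ts$ends, p, sep = "\t")
    outputs <- c(outputs, p)
  }

  manifest$outputs <- as.list(tools::md5sum(outputs))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
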