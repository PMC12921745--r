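#' Protein sequence coverage by accepted peptides
#'
#' Percent of residues covered by at least one exact substring occurrence of
#' any peptide; all occurrences count, overlaps union rather than sum.
#' Peptides are plain sequences (modifications stripped). Peptides with no
#' occurrence contribute nothing and are reported in the `unmatched`
#' attribute.
#'
#' @param protein a protein sequence string, or a one-row FASTA entry
#'   data.frame with a `sequence` column.
#' @param peptides character vector of peptide sequences.
#' @return percent covered (0..100) with attribute `unmatched`.
#' @export
compute_coverage <- function(protein, peptides) {
  seq <- if (is.data.frame(protein)) protein$sequence[1] else protein
  L <- nchar(seq)
  covered <- logical(L)
  unmatched <- character()
  for (pep in unique(peptides[nzchar(peptides)])) {
    hits <- gregexpr(pep, seq, fixed = TRUE)[[1]]
    if (hits[1] == -1L) {
      unmatched <- c(unmatched, pep)
      next
    }
    for (h in hits) covered[h:(h + nchar(pep) - 1L)] <- TRUE
  }
  structure(100 * sum(covered) / L, unmatched = unmatched)
}

#' Coverage table before and after the PTM search
#'
#' @param proteome data.frame of FASTA entries.
#' @param peptides_before peptides from the standard search.
#' @param peptides_after additional (e.g. modified, sequence-stripped)
#'   peptides; coverage "after" uses the union of both sets.
#' @return data.frame with per-protein coverage percentages.
#' @export
coverage_table <- function(proteome, peptides_before, peptides_after) {
  real <- proteome[proteome$origin == "real", , drop = FALSE]
  before <- vapply(real$sequence, function(s) {
    as.numeric(compute_coverage(s, peptides_before))
  }, 0, USE.NAMES = FALSE)
  after <- vapply(real$sequence, function(s) {
    as.numeric(compute_coverage(s, unique(c(peptides_before,
                                            peptides_after))))
  }, 0, USE.NAMES = FALSE)
  data.frame(accession = real$accession, coverage_standard = before,
             coverage_with_ptm = after, stringsAsFactors = FALSE)
}

.site_excluded_ptms <- c("oxidation", "carbamidomethyl")

#' Summaries and site table for accepted PTM results
#'
#' Per-PTM counts of accepted PSMs, distinct modified peptides (annotated
#' peptide strings) and distinct proteins, plus a modification-site table
#' (accession, residue, position, supporting PSM count). Fixed
#' carbamidomethylation and variable methionine oxidation are excluded from
#' the site table. When a proteome is supplied, peptide positions are
#' translated to protein coordinates via the first exact occurrence.
#'
#' @param accepted named list: ptm name -> data.frame of accepted records
#'   (canonical columns incl. `proteins`).
#' @param proteome optional data.frame of FASTA entries for site
#'   coordinates.
#' @param protein_sep accession separator in `proteins`.
#' @return list with `summary` (one row per PTM) and `sites`.
#' @export
summarize_ptm_counts <- function(accepted, proteome = NULL,
                                 protein_sep = ";") {
  stopifnot(!is.null(names(accepted)))
  summary <- do.call(rbind, lapply(names(accepted), function(ptm) {
    tab <- accepted[[ptm]]
    if (nrow(tab) == 0L) {
      return(data.frame(ptm = ptm, n_psms = 0L, n_peptides = 0L,
                        n_proteins = 0L, stringsAsFactors = FALSE))
    }
    modpep <- paste0(tab$peptide, "|", tab$modifications)
    prots <- unique(unlist(.split_proteins(tab$proteins, protein_sep)))
    prots <- prots[nzchar(prots) &
                     fasta_origin(prots) %in% c("real")]
    data.frame(ptm = ptm, n_psms = nrow(tab),
               n_peptides = length(unique(modpep)),
               n_proteins = length(prots), stringsAsFactors = FALSE)
  }))
  sites <- .site_table(accepted, proteome, protein_sep)
  list(summary = summary, sites = sites)
}

.site_table <- function(accepted, proteome, protein_sep) {
  rows <- list()
  for (ptm in names(accepted)) {
    tab <- accepted[[ptm]]
    if (nrow(tab) == 0L) next
    mods <- parse_modifications(tab$modifications)
    for (i in seq_len(nrow(tab))) {
      df <- mods[[i]]
      df <- df[!(df$ptm_name %in% .site_excluded_ptms), , drop = FALSE]
      if (nrow(df) == 0L) next
      prots <- .split_proteins(tab$proteins[i], protein_sep)[[1]]
      prots <- prots[fasta_origin(prots) == "real"]
      if (length(prots) == 0L) prots <- NA_character_
      for (acc in prots) {
        ppos <- rep(NA_integer_, nrow(df))
        if (!is.null(proteome) && !is.na(acc)) {
          j <- match(acc, proteome$accession)
          if (!is.na(j)) {
            at <- regexpr(tab$peptide[i], proteome$sequence[j], fixed = TRUE)
            if (at > 0L) ppos <- as.integer(at) + df$position - 1L
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          accession = acc, ptm_name = df$ptm_name, residue = df$residue,
          peptide = tab$peptide[i], peptide_position = df$position,
          protein_position = ppos, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(accession = character(), ptm_name = character(),
                      residue = character(), peptide_position = integer(),
                      protein_position = integer(), n_psms = integer(),
                      stringsAsFactors = FALSE))
  }
  all_rows <- do.call(rbind, rows)
  dt <- data.table::as.data.table(all_rows)
  out <- dt[, list(n_psms = .N),
            by = c("accession", "ptm_name", "residue", "peptide",
                   "peptide_position", "protein_position")]
  data.table::setorderv(out, c("accession", "ptm_name", "protein_position",
                               "peptide_position"))
  as.data.frame(out)
}

#' Run the per-PTM transferred-FDR pipeline
#'
#' For each PTM independently: merge the unmodified PSMs of the standard
#' search with the modified PSMs of that PTM's search, rank by score, fit
#' the gamma model (per `fdr_method`), compute the group-specific FDR and
#' q-values, accept at `alpha`, and strip PSMs mapping only to random
#' (entrapment) proteins. Every PTM is evaluated against the same
#' standard-search background; no cross-PTM correction is applied.
#'
#' @param standard_table canonical PSM records of the standard search (path
#'   or data.frame).
#' @param ptm_tables named list: ptm name -> records of that PTM's search
#'   (path or data.frame).
#' @param alpha acceptance level (default 0.01).
#' @param fdr_method `"spline_transferred"` (default), `"linear_transferred"`
#'   or `"separate"`.
#' @param sigma_cutoff error-propagation cutoff for the stable mask.
#' @param smoothing_sigma Gaussian width for the inflection search (default
#'   2% of the grid span).
#' @param n_interior_knots interior knots for the spline (anchor included).
#' @param key_profile key fields for the combined-results table.
#' @param grid threshold grid spec (see [threshold_grid()]).
#' @param n_definition numerator convention of the transferred FDR.
#' @param proteome optional FASTA entries (data.frame or path) for site
#'   coordinates and coverage.
#' @param output_dir optional directory; when given, all result tables are
#'   written there as TSV/CSV.
#' @param exclude_standard_keys drop modified PSMs whose spectrum key (file,
#'   scan) already appears in the standard search before merging.
#' @return list with `per_ptm` (annotations, model, curves, threshold per
#'   PTM), `summary`, `sites`, `combined` (all accepted PSMs), and
#'   `coverage` (when a proteome is given).
#' @export
run_ptm_fdr_pipeline <- function(standard_table, ptm_tables, alpha = 0.01,
                                 fdr_method = c("spline_transferred",
                                                "linear_transferred",
                                                "separate"),
                                 sigma_cutoff = 0.01, smoothing_sigma = NULL,
                                 n_interior_knots = 3L,
                                 key_profile = c("file", "scan", "peptide"),
                                 grid = "decoy",
                                 n_definition = "unmodified",
                                 proteome = NULL, output_dir = NULL,
                                 exclude_standard_keys = FALSE) {
  fdr_method <- match.arg(fdr_method)
  stopifnot(alpha > 0, alpha < 1)
  std <- if (is.character(standard_table)) read_psm_table(standard_table)
         else data.table::as.data.table(standard_table)
  if (is.null(names(ptm_tables)) || any(!nzchar(names(ptm_tables)))) {
    stop("ptm_tables must be a named list (ptm name -> table)",
         call. = FALSE)
  }
  if (!is.null(proteome) && is.character(proteome)) {
    proteome <- read_fasta(proteome)
  }
  background <- std[!std$is_modified, ]

  per_ptm <- lapply(names(ptm_tables), function(ptm) {
    tab <- ptm_tables[[ptm]]
    tab <- if (is.character(tab)) read_psm_table(tab, ptm = ptm)
           else data.table::as.data.table(tab)
    modified <- tab[tab$is_modified, ]
    if (exclude_standard_keys && nrow(modified)) {
      std_keys <- spectrum_keys(std, c("file", "scan"))
      modified <- modified[!spectrum_keys(modified, c("file", "scan")) %in%
                             std_keys, ]
    }
    if (sum(!modified$is_decoy) == 0L) {
      warning("PTM '", ptm, "': no modified target PSMs; skipping",
              call. = FALSE)
      return(list(ptm = ptm, annotations = NULL, model = NULL,
                  curves = NULL, threshold_rank = NA_integer_,
                  accepted = NULL))
    }
    merged <- rbind(background, modified, fill = TRUE)
    ranked <- rank_psms(merged)
    sep <- separate_fdr_curve(ranked)
    sep_res <- qvalues_and_threshold(sep, alpha = alpha, ranked = ranked)

    model <- NULL; curves <- NULL; gcurve <- NULL
    if (fdr_method == "separate") {
      res <- sep_res
    } else {
      curves <- count_curves(ranked, grid = grid)
      res <- tryCatch({
        gcurve <- estimate_gamma_curve(curves, sigma_cutoff = sigma_cutoff)
        model <- if (fdr_method == "spline_transferred") {
          anchor <- find_inflection_rank(decoy_target_ratio(curves),
                                         smoothing_sigma = smoothing_sigma)
          suppressWarnings(
            fit_spline_linear_gamma(gcurve, anchor,
                                    n_interior_knots = n_interior_knots))
        } else {
          fit_linear_gamma(gcurve)
        }
        tf <- transferred_fdr_curve(curves, model,
                                    n_definition = n_definition)
        qvalues_and_threshold(tf, alpha = alpha, ranked = ranked)
      }, error = function(e) {
        warning("PTM '", ptm, "': ", conditionMessage(e),
                "; no PSMs accepted", call. = FALSE)
        NULL
      })
      if (is.null(res)) {
        res <- list(curve = NULL, threshold_rank = NA_integer_,
                    alpha = alpha, annotations = sep_res$annotations)
        if (!is.null(res$annotations)) {
          res$annotations$transferred_fdr <- NA_real_
          res$annotations$q_value <- NA_real_
          res$annotations$accepted <- FALSE
        }
      }
    }
    ann <- res$annotations
    if (!is.null(ann)) {
      sepann <- sep_res$annotations
      if (!is.null(sepann)) {
        key <- paste(ann$file, ann$scan, ann$rank)
        skey <- paste(sepann$file, sepann$scan, sepann$rank)
        ann$separate_q <- sepann$q_value[match(key, skey)]
      } else {
        ann$separate_q <- NA_real_
      }
      ann <- cbind(ptm = ptm, ann)
    }
    accepted <- if (!is.null(ann)) {
      strip_random_hits(ann[ann$accepted, ])
    } else NULL
    list(ptm = ptm, annotations = ann, model = model, curves = curves,
         gamma_curve = gcurve, threshold_rank = res$threshold_rank,
         accepted = accepted)
  })
  names(per_ptm) <- names(ptm_tables)

  accepted_list <- lapply(per_ptm, function(p) {
    if (is.null(p$accepted)) {
      data.table::data.table(peptide = character(),
                             modifications = character(),
                             proteins = character())
    } else p$accepted
  })
  counts <- summarize_ptm_counts(accepted_list, proteome = proteome)
  summary <- counts$summary
  summary$threshold_rank <- vapply(per_ptm, function(p) {
    as.integer(p$threshold_rank %||% NA_integer_)
  }, 0L)
  summary$model_r2 <- vapply(per_ptm, function(p) {
    if (is.null(p$model)) NA_real_ else p$model$r2
  }, 0)
  summary$model_rmse <- vapply(per_ptm, function(p) {
    if (is.null(p$model)) NA_real_ else p$model$rmse
  }, 0)
  combined <- data.table::rbindlist(
    Filter(function(a) !is.null(a) && nrow(a) > 0,
           lapply(per_ptm, `[[`, "accepted")), fill = TRUE)

  coverage <- NULL
  if (!is.null(proteome)) {
    std_peps <- unique(std$peptide[!std$is_decoy])
    mod_peps <- if (nrow(combined)) unique(combined$peptide) else character()
    coverage <- coverage_table(proteome, std_peps, mod_peps)
  }
  out <- list(per_ptm = per_ptm, summary = summary, sites = counts$sites,
              combined = combined, coverage = coverage, alpha = alpha,
              fdr_method = fdr_method)
  if (!is.null(output_dir)) .write_pipeline_outputs(out, output_dir)
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

.write_pipeline_outputs <- function(res, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  fw <- function(x, name, sep = "\t") {
    if (is.null(x)) return(invisible())
    data.table::fwrite(x, file.path(output_dir, name), sep = sep,
                       quote = FALSE)
  }
  for (ptm in names(res$per_ptm)) {
    p <- res$per_ptm[[ptm]]
    if (!is.null(p$annotations)) fw(p$annotations,
                                    paste0(ptm, "_psms.tsv"))
    if (!is.null(p$gamma_curve)) {
      cur <- merge(as.data.frame(p$curves), as.data.frame(p$gamma_curve)[
        , c("threshold", "gamma_hat", "sigma", "stable")], by = "threshold")
      fw(cur, paste0(ptm, "_curve.tsv"))
    }
    if (!is.null(p$model)) {
      m <- p$model
      fw(data.frame(segment = seq_along(m$a),
                    x_left = m$nodes[-length(m$nodes)],
                    x_right = m$nodes[-1], a = m$a, b = m$b,
                    anchor = m$anchor %||% NA_real_, r2 = m$r2,
                    rmse = m$rmse),
         paste0(ptm, "_model.tsv"))
    }
  }
  if (nrow(res$combined)) fw(res$combined, "accepted_combined.tsv")
  fw(res$summary, "ptm_summary.csv", sep = ",")
  fw(res$sites, "ptm_sites.csv", sep = ",")
  if (!is.null(res$coverage)) fw(res$coverage, "protein_coverage.csv",
                                 sep = ",")
  invisible(output_dir)
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Repeated keys of
#' the form `ptm.<name>` collect into a named `ptm_tables` list.
#'
#' @param path configuration file path.
#' @return named list of character values (plus `ptm_tables` when present).
#' @export
read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[`, "", 2L))
  vals <- trimws(vapply(kv, `[`, "", 3L))
  out <- as.list(vals)
  names(out) <- keys
  ptm_keys <- grep("^ptm\\.", keys)
  if (length(ptm_keys)) {
    ptm_tables <- as.list(vals[ptm_keys])
    names(ptm_tables) <- sub("^ptm\\.", "", keys[ptm_keys])
    out <- out[-ptm_keys]
    out$ptm_tables <- ptm_tables
  }
  out
}
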