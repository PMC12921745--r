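#' PTM specification
#'
#' Identifies one modification type for a search run: its normalized name,
#' the residues it targets, and its monoisotopic mass delta.
#'
#' @param name normalized PTM name (e.g. `"phospho"`, `"acetyl"`).
#' @param target_residues character vector of one-letter residues (or the
#'   terminus markers `"N-term"`, `"C-term"`).
#' @param mass_delta mass shift in Da.
#' @return an object of class `ptm_spec`.
#' @export
ptm_spec <- function(name, target_residues, mass_delta) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(target_residues) == 0L) {
    stop("target_residues must be non-empty", call. = FALSE)
  }
  structure(list(name = name, target_residues = target_residues,
                 mass_delta = mass_delta), class = "ptm_spec")
}

#' Packaged PTM name vocabulary
#'
#' Mapping table that normalizes UniProt `MOD_RES` feature notes and dbPTM
#' modification types to the controlled names used in this package, with the
#' affected residue and mass delta where determined by the source name.
#'
#' @return data.frame with columns `source_name`, `ptm_name`, `residue`,
#'   `mass_delta`.
#' @export
ptm_vocabulary <- function() {
  path <- system.file("extdata", "ptm_vocabulary.tsv", package = "ptmfdr")
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
}

.map_ptm_name <- function(raw, vocab) {
  i <- match(tolower(raw), tolower(vocab$source_name))
  list(ptm_name = ifelse(is.na(i), raw, vocab$ptm_name[i]),
       residue = ifelse(is.na(i), NA_character_, vocab$residue[i]),
       mapped = !is.na(i))
}

#' Parse UniProt modified-residue annotations
#'
#' Reads UniProt flat-text records and extracts one annotation record per
#' `FT MOD_RES` feature, normalizing the feature note through the packaged
#' vocabulary. Malformed feature lines are skipped with a warning and
#' counted in the parse report (attribute `report`).
#'
#' @param path UniProt flat-format text file.
#' @param vocab vocabulary table, see [ptm_vocabulary()].
#' @return data.frame with `accession`, `position`, `residue`, `ptm_name`,
#'   `source`, `mapped`; attribute `report` holds feature/skip counts.
#' @export
parse_uniprot_ptm_annotations <- function(path, vocab = ptm_vocabulary()) {
  lines <- readLines(path)
  acc <- NA_character_
  recs <- list()
  pending_pos <- NA_integer_
  n_feat <- 0L; n_skip <- 0L
  flush_pending <- function() {
    if (!is.na(pending_pos)) {  # MOD_RES without a /note qualifier
      n_skip <<- n_skip + 1L
      warning("MOD_RES feature without /note near accession ", acc,
              call. = FALSE)
    }
    pending_pos <<- NA_integer_
  }
  for (ln in lines) {
    if (startsWith(ln, "AC") && is.na(acc)) {
      acc <- sub(";.*$", "", trimws(sub("^AC\\s+", "", ln)))
    } else if (startsWith(ln, "//")) {
      flush_pending()
      acc <- NA_character_
    } else if (grepl("^FT\\s+MOD_RES\\s", ln)) {
      flush_pending()
      n_feat <- n_feat + 1L
      pos <- trimws(sub("^FT\\s+MOD_RES", "", ln))
      if (grepl("^[0-9]+$", pos)) {
        pending_pos <- as.integer(pos)
      } else {
        n_skip <- n_skip + 1L
        warning("malformed MOD_RES position '", pos, "' for accession ", acc,
                call. = FALSE)
      }
    } else if (grepl("^FT\\s+/note=", ln) && !is.na(pending_pos)) {
      note <- sub("^FT\\s+/note=\"?", "", ln)
      note <- sub("\"?;?\\s*$", "", note)
      note <- sub("[;.].*$", "", note)   # strip isoform/evidence tails
      m <- .map_ptm_name(note, vocab)
      recs[[length(recs) + 1L]] <- data.frame(
        accession = acc, position = pending_pos, residue = m$residue,
        ptm_name = m$ptm_name, source = "uniprot", mapped = m$mapped,
        stringsAsFactors = FALSE)
      pending_pos <- NA_integer_
    }
  }
  flush_pending()
  out <- if (length(recs)) do.call(rbind, recs)
         else data.frame(accession = character(), position = integer(),
                         residue = character(), ptm_name = character(),
                         source = character(), mapped = logical(),
                         stringsAsFactors = FALSE)
  attr(out, "report") <- list(n_features = n_feat, n_skipped = n_skip,
                              n_unmapped = sum(!out$mapped))
  out
}

#' Parse a dbPTM-style annotation table
#'
#' Tab-separated records with entry name, accession, position, modification
#' type, and optionally evidence and a sequence window. Unknown modification
#' types are kept with their raw name and flagged unmapped; rows with
#' positions below 1 are rejected with a warning naming the row.
#'
#' @param path dbPTM-style TSV (no header).
#' @param vocab vocabulary table, see [ptm_vocabulary()].
#' @return data.frame as in [parse_uniprot_ptm_annotations()] with
#'   `source = "dbptm"`; the residue is read from the centre of the
#'   sequence-window column when present.
#' @export
parse_dbptm_table <- function(path, vocab = ptm_vocabulary()) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 4L) {
    stop("dbPTM table needs at least 4 columns ",
         "(entry, accession, position, type)", call. = FALSE)
  }
  pos <- suppressWarnings(as.integer(raw[[3]]))
  bad <- which(is.na(pos) | pos < 1L)
  if (length(bad)) {
    warning("rejected row(s) with invalid position: ",
            paste(bad, collapse = ", "), call. = FALSE)
  }
  keep <- setdiff(seq_len(nrow(raw)), bad)
  if (length(keep) == 0L) {
    out <- data.frame(accession = character(), position = integer(),
                      residue = character(), ptm_name = character(),
                      source = character(), mapped = logical(),
                      stringsAsFactors = FALSE)
    attr(out, "report") <- list(n_rows = nrow(raw), n_rejected = length(bad),
                                n_unmapped = 0L)
    return(out)
  }
  m <- .map_ptm_name(raw[[4]][keep], vocab)
  residue <- m$residue
  if (ncol(raw) >= 6L) {   # centre residue of the sequence window
    win <- as.character(raw[[6]][keep])
    centre <- substr(win, (nchar(win) + 1L) %/% 2L, (nchar(win) + 1L) %/% 2L)
    residue <- ifelse(is.na(residue) & nzchar(win), centre, residue)
  }
  out <- data.frame(accession = as.character(raw[[2]][keep]),
                    position = pos[keep], residue = residue,
                    ptm_name = m$ptm_name, source = "dbptm",
                    mapped = m$mapped, stringsAsFactors = FALSE)
  attr(out, "report") <- list(n_rows = nrow(raw), n_rejected = length(bad),
                              n_unmapped = sum(!out$mapped))
  out
}

#' Select proteins to search for one PTM
#'
#' Keeps accessions that were identified in the standard search and carry at
#' least one annotation of the PTM on one of its target residues; the
#' `extra` custom list is included unconditionally (its proteins are
#' searched whether annotated or not). Duplicates across annotation sources
#' collapse to one accession.
#'
#' @param annotations annotation records from the parsers above (rbind-able).
#' @param ptm a [ptm_spec()].
#' @param identified accessions from the standard search.
#' @param extra custom accession list, included regardless of annotation.
#' @return sorted, de-duplicated character vector of accessions.
#' @export
select_ptm_proteins <- function(annotations, ptm, identified,
                                extra = character()) {
  hit <- annotations$ptm_name == ptm$name &
    (is.na(annotations$residue) |
       annotations$residue %in% ptm$target_residues)
  annotated <- unique(annotations$accession[hit])
  out <- sort(unique(c(intersect(identified, annotated), extra)))
  if (length(out) == 0L) {
    warning("no proteins selected for PTM '", ptm$name,
            "'; the database will contain random sequences only",
            call. = FALSE)
  }
  out
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate random (entrapment) protein sequences
#'
#' Random proteins pad a reduced search database so decoy statistics remain
#' well populated. Lengths are resampled from an empirical length
#' distribution and residues drawn i.i.d. from a composition vector, so the
#' random peptide mass distribution tracks the proteome's.
#'
#' @param n number of sequences.
#' @param composition named probability vector over the 20 amino acids
#'   (must sum to 1 within 1e-9).
#' @param length_sampler numeric vector of empirical lengths to resample, or
#'   a `function(n)` returning lengths.
#' @param seed integer seed for reproducible output (caller RNG state is
#'   preserved).
#' @param prefix accession prefix for the generated entries.
#' @return data.frame of FASTA entries with `origin = "random"`.
#' @export
generate_random_proteins <- function(n, composition, length_sampler,
                                     seed = NULL, prefix = "RND_") {
  stopifnot(n >= 0)
  if (abs(sum(composition) - 1) > 1e-9) {
    stop("composition must sum to 1 (got ", format(sum(composition)), ")",
         call. = FALSE)
  }
  if (n == 0L) {
    return(data.frame(accession = character(), description = character(),
                      sequence = character(), origin = character(),
                      stringsAsFactors = FALSE))
  }
  aa <- names(composition)
  .with_seed(seed, {
    lens <- if (is.function(length_sampler)) length_sampler(n)
            else sample(length_sampler, n, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(aa, L, replace = TRUE, prob = composition), collapse = "")
    }, "")
    data.frame(accession = sprintf("%s%05d", prefix, seq_len(n)),
               description = "random protein", sequence = seqs,
               origin = "random", stringsAsFactors = FALSE)
  })
}

#' Reversed decoy entries
#'
#' Full-sequence reversal, the decoy construction mirrored by the reversed
#' random sequences. Accessions gain (or, when already prefixed, lose) the
#' decoy prefix, so the operation is an involution on the sequence; origins
#' map real <-> decoy and random <-> random_decoy.
#'
#' @param entries data.frame of FASTA entries.
#' @param decoy_prefix accession prefix for decoys.
#' @return data.frame of decoy entries.
#' @export
reverse_decoy <- function(entries, decoy_prefix = "DECOY_") {
  rev_seq <- as.character(Biostrings::reverse(
    Biostrings::AAStringSet(entries$sequence)))
  prefixed <- startsWith(entries$accession, decoy_prefix)
  origin_map <- c(real = "decoy", random = "random_decoy",
                  decoy = "real", random_decoy = "random")
  data.frame(
    accession = ifelse(prefixed,
                       substring(entries$accession, nchar(decoy_prefix) + 1L),
                       paste0(decoy_prefix, entries$accession)),
    description = entries$description,
    sequence = rev_seq,
    origin = unname(origin_map[entries$origin]),
    stringsAsFactors = FALSE)
}

#' Amino-acid composition of a set of sequences
#'
#' @param sequences character vector of amino-acid sequences.
#' @return named probability vector over the 20 standard amino acids.
#' @export
proteome_composition <- function(sequences) {
  aa <- strsplit(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                   "R","S","T","V","W","Y"), "")
  aa <- unlist(aa)
  counts <- colSums(Biostrings::letterFrequency(
    Biostrings::AAStringSet(sequences), letters = aa))
  counts / sum(counts)
}

#' Database build specification
#'
#' @param ptm a [ptm_spec()].
#' @param annotated_accessions accessions to include as real entries.
#' @param n_random number of random forward sequences (default 5000; their
#'   reverses are added too).
#' @param seed integer seed for the random sequences.
#' @param composition optional composition vector; defaults to the
#'   proteome's at build time.
#' @param length_sampler optional length source; defaults to the proteome's
#'   empirical lengths.
#' @param decoy_prefix,random_prefix accession prefixes.
#' @return an object of class `database_spec`.
#' @export
database_spec <- function(ptm, annotated_accessions, n_random = 5000L,
                          seed = 1L, composition = NULL,
                          length_sampler = NULL, decoy_prefix = "DECOY_",
                          random_prefix = "RND_") {
  stopifnot(n_random >= 0L)
  structure(list(ptm = ptm, annotated_accessions = annotated_accessions,
                 n_random = as.integer(n_random), seed = seed,
                 composition = composition, length_sampler = length_sampler,
                 decoy_prefix = decoy_prefix, random_prefix = random_prefix,
                 decoy_mode = "reverse"),
            class = "database_spec")
}

#' Build a reduced PTM search database
#'
#' Assembles the FASTA for one PTM-specific search: the annotated real
#' proteins, `n_random` random forward sequences, the reverses of those
#' randoms, and reversed decoys of the real proteins — in that order.
#' Deterministic under the spec's seed.
#'
#' @param spec a [database_spec()].
#' @param proteome data.frame of FASTA entries resolving every annotated
#'   accession.
#' @return data.frame of FASTA entries with a `manifest` attribute (counts
#'   by origin, seed, composition).
#' @export
build_ptm_fasta <- function(spec, proteome) {
  idx <- match(spec$annotated_accessions, proteome$accession)
  if (anyNA(idx)) {
    stop("accessions not found in the proteome: ",
         paste(spec$annotated_accessions[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  real <- proteome[idx, c("accession", "description", "sequence"),
                   drop = FALSE]
  real$origin <- "real"
  composition <- spec$composition
  if (is.null(composition)) composition <- proteome_composition(proteome$sequence)
  length_sampler <- spec$length_sampler
  if (is.null(length_sampler)) length_sampler <- nchar(proteome$sequence)
  randoms <- generate_random_proteins(spec$n_random, composition,
                                      length_sampler, seed = spec$seed,
                                      prefix = spec$random_prefix)
  out <- rbind(real, randoms,
               if (nrow(randoms)) reverse_decoy(randoms, spec$decoy_prefix),
               reverse_decoy(real, spec$decoy_prefix))
  rownames(out) <- NULL
  attr(out, "manifest") <- data.frame(
    ptm = spec$ptm$name,
    n_real = nrow(real), n_random = spec$n_random,
    n_random_decoy = nrow(randoms), n_decoy = nrow(real),
    seed = spec$seed,
    composition = paste(sprintf("%s=%.5f", names(composition), composition),
                        collapse = ";"),
    stringsAsFactors = FALSE)
  out
}

#' Remove randoms-only hits from thresholded results
#'
#' After the FDR threshold is fixed, PSMs whose every protein assignment is
#' a random (entrapment) sequence or its decoy are removed; the threshold is
#' never recomputed. PSMs sharing at least one real protein are kept.
#' Idempotent.
#'
#' @param records data.frame of PSM records (or FDR annotations) with a
#'   `proteins` column.
#' @param random_prefix,decoy_prefix,protein_sep accession conventions.
#' @return the filtered records.
#' @export
strip_random_hits <- function(records, random_prefix = "RND_",
                              decoy_prefix = "DECOY_", protein_sep = ";") {
  if (nrow(records) == 0L) return(records)
  plist <- .split_proteins(records$proteins, protein_sep)
  all_random <- vapply(plist, function(p) {
    length(p) > 0L &&
      all(fasta_origin(p, decoy_prefix, random_prefix) %in%
            c("random", "random_decoy"))
  }, NA)
  records[!all_random, , drop = FALSE]
}

#' Search-space sizing harness
#'
#' Compares PTM search results obtained against databases of different
#' sizes: per-size q-value distribution summaries for modified target PSMs
#' (subset-only target-decoy q-values), the survivors of a q <= 0.05
#' filter, and the core/unique partition of those survivors under the
#' (file, scan, modified peptide) key profile.
#'
#' @param psm_tables named list: size label -> canonical PSM records
#'   (data.frame) or a path readable by [read_psm_table()].
#' @param q_cutoff significance filter (default 0.05).
#' @param key_profile key fields for the partition.
#' @return list with `summaries` (one row per size), `core` (keys found at
#'   every size) and `unique` (named list of keys found only at that size).
#' @export
search_space_experiment <- function(psm_tables, q_cutoff = 0.05,
                                    key_profile = c("file", "scan",
                                                    "peptide")) {
  if (is.null(names(psm_tables)) || any(!nzchar(names(psm_tables)))) {
    stop("psm_tables must be a named list (size label -> table)",
         call. = FALSE)
  }
  tables <- lapply(psm_tables, function(t) {
    if (is.character(t)) read_psm_table(t) else data.table::as.data.table(t)
  })
  per_size <- lapply(names(tables), function(lab) {
    tab <- tables[[lab]]
    ranked <- rank_psms(tab)
    sep <- separate_fdr_curve(ranked)
    ann <- qvalues_and_threshold(sep, alpha = q_cutoff,
                                 ranked = ranked)$annotations
    if (is.null(ann)) {
      ann <- data.table::data.table(q_value = numeric(),
                                    accepted = logical())
    }
    q <- ann$q_value[!is.na(ann$q_value)]
    acc <- ann[!is.na(ann$q_value) & ann$q_value <= q_cutoff, ]
    list(summary = data.frame(
           size = lab, n_modified_targets = nrow(ann),
           mean_q = if (length(q)) mean(q) else NA_real_,
           q25 = if (length(q)) unname(stats::quantile(q, 0.25)) else NA_real_,
           median_q = if (length(q)) stats::median(q) else NA_real_,
           q75 = if (length(q)) unname(stats::quantile(q, 0.75)) else NA_real_,
           n_significant = nrow(acc), stringsAsFactors = FALSE),
         keys = unique(spectrum_keys(acc, key_profile)))
  })
  names(per_size) <- names(tables)
  keys <- lapply(per_size, `[[`, "keys")
  core <- Reduce(intersect, keys)
  uniq <- lapply(names(keys), function(lab) {
    others <- unlist(keys[setdiff(names(keys), lab)], use.names = FALSE)
    setdiff(keys[[lab]], others)
  })
  names(uniq) <- names(keys)
  list(summaries = do.call(rbind, lapply(per_size, `[[`, "summary")),
       core = core, unique = uniq)
}
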