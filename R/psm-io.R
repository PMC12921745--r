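#' Column-mapping dialect for PSM tables
#'
#' Search engines export peptide-spectrum matches (PSMs) with differing column
#' names. A dialect maps the canonical fields used throughout this package to
#' the column names of a particular export, so any engine's tab-separated
#' output can be adapted without rewriting it.
#'
#' Mandatory fields are `file`, `scan`, `peptide` and `score`. The decoy
#' status may come from a dedicated column (`decoy`) or be derived from the
#' protein accession prefix (`decoy_prefix`); when both are available they
#' must agree. `modified` is optional: when absent, the modified status is
#' derived from the parsed modification annotation (see
#' [read_psm_table()]).
#'
#' @param file,scan,charge,peptide,modifications,score,decoy,modified,proteins
#'   column names in the table for each canonical field; set to `NA` to mark
#'   a field as absent.
#' @param decoy_prefix accession prefix identifying decoy proteins.
#' @param random_prefix accession prefix identifying random (entrapment)
#'   proteins.
#' @param protein_sep separator joining multiple protein accessions in one
#'   cell.
#' @return an object of class `psm_dialect`.
#' @export
psm_dialect <- function(file = "file", scan = "scan", charge = "charge",
                        peptide = "peptide", modifications = "modifications",
                        score = "score", decoy = "is_decoy",
                        modified = "is_modified", proteins = "proteins",
                        decoy_prefix = "DECOY_", random_prefix = "RND_",
                        protein_sep = ";") {
  structure(list(file = file, scan = scan, charge = charge,
                 peptide = peptide, modifications = modifications,
                 score = score, decoy = decoy, modified = modified,
                 proteins = proteins, decoy_prefix = decoy_prefix,
                 random_prefix = random_prefix, protein_sep = protein_sep),
            class = "psm_dialect")
}

.canonical_cols <- c("file", "scan", "charge", "peptide", "modifications",
                     "score", "is_decoy", "is_modified", "proteins")

#' Parse inline modification annotations
#'
#' Modification tokens follow the syntax `residue``position``[name``+delta``]`,
#' e.g. `"S7[phospho+79.9663]"`, multiple tokens joined by `";"`. Terminal
#' modifications use `N-term[...]` (position 0) or `C-term[...]` (position
#' recorded as -1).
#'
#' @param x character vector of annotation strings (`""` or `NA` = none).
#' @return a list of data.frames with columns `position`, `residue`,
#'   `ptm_name`, `mass_delta` (zero rows for unmodified entries).
#' @export
parse_modifications <- function(x) {
  rx <- "^(N-term|C-term|[A-Z])([0-9]+)?\\[([^]+-]+)([+-][0-9]*\\.?[0-9]+)\\]$"
  empty <- data.frame(position = integer(), residue = character(),
                      ptm_name = character(), mass_delta = numeric(),
                      stringsAsFactors = FALSE)
  lapply(seq_along(x), function(i) {
    s <- x[[i]]
    if (is.na(s) || !nzchar(s)) return(empty)
    toks <- strsplit(s, ";", fixed = TRUE)[[1]]
    toks <- toks[nzchar(toks)]
    m <- regmatches(toks, regexec(rx, toks))
    bad <- vapply(m, length, 1L) != 5L
    if (any(bad)) {
      stop(sprintf("row %d: unparseable modification token(s): %s",
                   i, paste(toks[bad], collapse = ", ")), call. = FALSE)
    }
    res <- vapply(m, `[`, "", 2L)
    pos <- vapply(m, `[`, "", 3L)
    position <- ifelse(res == "N-term", 0L,
                       ifelse(res == "C-term", -1L, as.integer(pos)))
    if (anyNA(position)) {
      stop(sprintf("row %d: modification token missing position", i),
           call. = FALSE)
    }
    data.frame(position = as.integer(position),
               residue = ifelse(res %in% c("N-term", "C-term"), NA, res),
               ptm_name = vapply(m, `[`, "", 4L),
               mass_delta = as.numeric(vapply(m, `[`, "", 5L)),
               stringsAsFactors = FALSE)
  })
}

#' Format parsed modifications back to annotation strings
#'
#' Inverse of [parse_modifications()]; `format_modifications(parse_modifications(x))`
#' reproduces `x` up to numeric formatting of the mass delta.
#'
#' @param mods list of modification data.frames.
#' @return character vector of annotation strings.
#' @export
format_modifications <- function(mods) {
  vapply(mods, function(df) {
    if (nrow(df) == 0L) return("")
    res <- ifelse(df$position == 0L, "N-term",
                  ifelse(df$position == -1L, "C-term", df$residue))
    pos <- ifelse(df$position > 0L, as.character(df$position), "")
    delta <- vapply(df$mass_delta, format, "", trim = TRUE,
                    scientific = FALSE, digits = 10)
    delta <- ifelse(df$mass_delta >= 0, paste0("+", delta), delta)
    paste0(res, pos, "[", df$ptm_name, delta, "]", collapse = ";")
  }, "")
}

.is_decoy_accession <- function(acc, decoy_prefix) {
  startsWith(acc, decoy_prefix)
}

.split_proteins <- function(x, sep) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  strsplit(x, sep, fixed = TRUE)
}

.chr_or_empty <- function(x, n) {
  if (is.null(x)) return(rep("", n))
  x <- as.character(x)
  x[is.na(x)] <- ""
  x
}

.as_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes", "decoy")
}

#' Read a PSM table
#'
#' Reads a tab-separated table of peptide-spectrum matches into the canonical
#' record layout: one row per PSM with `file`, `scan`, `charge`, `peptide`,
#' `modifications`, `score`, `is_decoy`, `is_modified` and `proteins`
#' columns.
#'
#' The decoy flag is taken from the mapped decoy column when present,
#' otherwise derived from the protein accessions: a PSM is a decoy when
#' every accession carries the decoy prefix. When both sources are present
#' they must agree row-by-row. The modified flag marks PSMs carrying the
#' search-specific PTM; methionine oxidation and fixed carbamidomethylation
#' do not count. It is taken from the mapped column when present, otherwise
#' derived from the parsed modification annotation (restricted to `ptm` when
#' given).
#'
#' @param path path to a TSV file with a header row.
#' @param dialect a [psm_dialect()] mapping canonical fields to columns.
#' @param ptm optional PTM name; when deriving `is_modified`, only this
#'   modification counts.
#' @return a `data.table` of PSM records.
#' @export
read_psm_table <- function(path, dialect = psm_dialect(), ptm = NULL) {
  if (!file.exists(path)) stop("PSM table not found: ", path, call. = FALSE)
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = dialect$file),
                           na.strings = "")
  mandatory <- c("file", "scan", "peptide", "score")
  for (f in mandatory) {
    col <- dialect[[f]]
    if (is.na(col) || !col %in% names(raw)) {
      stop(sprintf("mandatory column '%s' (field '%s') missing from %s",
                   col, f, path), call. = FALSE)
    }
  }
  has <- function(f) !is.na(dialect[[f]]) && dialect[[f]] %in% names(raw)
  if (!has("decoy") && !has("proteins")) {
    stop("no decoy column mapped and no protein column to derive it from",
         call. = FALSE)
  }
  n <- nrow(raw)
  out <- data.table::data.table(
    file = as.character(raw[[dialect$file]]),
    scan = as.integer(raw[[dialect$scan]]),
    charge = if (has("charge")) as.integer(raw[[dialect$charge]])
             else rep(NA_integer_, n),
    peptide = as.character(raw[[dialect$peptide]]),
    modifications = if (has("modifications"))
      .chr_or_empty(raw[[dialect$modifications]], n) else rep("", n),
    score = as.numeric(raw[[dialect$score]]),
    proteins = if (has("proteins"))
      .chr_or_empty(raw[[dialect$proteins]], n) else rep("", n)
  )
  if (n > 0 && any(is.na(out$scan) | out$scan < 0L)) {
    stop("scan numbers must be non-negative integers", call. = FALSE)
  }
  mods <- parse_modifications(out$modifications)

  prot_list <- .split_proteins(out$proteins, dialect$protein_sep)
  decoy_from_acc <- vapply(prot_list, function(p) {
    length(p) > 0L && all(.is_decoy_accession(p, dialect$decoy_prefix))
  }, NA)
  if (has("decoy")) {
    is_decoy <- .as_flag(raw[[dialect$decoy]])
    informative <- vapply(prot_list, length, 1L) > 0L
    disagree <- which(informative & (is_decoy != decoy_from_acc))
    if (length(disagree)) {
      stop(sprintf(
        "decoy column and accession prefix disagree at row(s): %s",
        paste(utils::head(disagree, 5L), collapse = ", ")), call. = FALSE)
    }
  } else {
    is_decoy <- decoy_from_acc
  }
  out$is_decoy <- is_decoy

  if (has("modified")) {
    out$is_modified <- .as_flag(raw[[dialect$modified]])
  } else {
    ignore <- c("oxidation", "carbamidomethyl")
    out$is_modified <- vapply(mods, function(df) {
      keep <- if (is.null(ptm)) !(df$ptm_name %in% ignore)
              else df$ptm_name == ptm
      any(keep)
    }, NA)
  }
  .validate_psm_table(out)
  out[]
}

.validate_psm_table <- function(x) {
  bad <- which(!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x$peptide))
  if (length(bad)) {
    stop(sprintf("invalid peptide sequence at row(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  mods <- parse_modifications(x$modifications)
  for (i in seq_along(mods)) {
    p <- mods[[i]]$position
    if (any(p > nchar(x$peptide[i]))) {
      stop(sprintf("row %d: modification position beyond peptide length", i),
           call. = FALSE)
    }
  }
  invisible(x)
}

#' Write a PSM table
#'
#' Writes canonical PSM records as TSV. `read_psm_table()` of the written
#' file reproduces the records field-for-field.
#'
#' @param records data.frame of canonical PSM records.
#' @param path output path.
#' @export
write_psm_table <- function(records, path) {
  records <- data.table::as.data.table(records)
  cols <- intersect(.canonical_cols, names(records))
  data.table::fwrite(records[, cols, with = FALSE], path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}

#' Spectrum-level primary keys
#'
#' Builds the unique identifier used to intersect PSM result sets. The key
#' profile selects which fields participate in equality: any subset of
#' `file`, `scan`, `charge` and `peptide`. The peptide component is the
#' *annotated* peptide string (sequence plus modification tokens), so the
#' same sequence with different modifications yields different keys.
#'
#' @param records data.frame of canonical PSM records.
#' @param key_profile character subset of `c("file","scan","charge","peptide")`.
#' @return character vector of keys, one per record.
#' @export
spectrum_keys <- function(records,
                          key_profile = c("file", "scan", "charge", "peptide")) {
  allowed <- c("file", "scan", "charge", "peptide")
  key_profile <- unique(key_profile)
  if (length(key_profile) == 0L) {
    stop("key_profile must name at least one field", call. = FALSE)
  }
  if (!all(key_profile %in% allowed)) {
    stop("key_profile fields must be among: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  }
  parts <- lapply(key_profile, function(f) {
    if (f == "peptide") {
      paste0(records$peptide,
             ifelse(nzchar(records$modifications),
                    paste0("|", records$modifications), ""))
    } else as.character(records[[f]])
  })
  do.call(paste, c(parts, sep = "\r"))
}

#' Intersect two PSM result sets
#'
#' Partitions the spectrum keys of two result sets into those found in both
#' (`core`) and those unique to either, under a configurable key profile.
#'
#' @param a,b data.frames of canonical PSM records.
#' @param key_profile fields participating in key equality; see
#'   [spectrum_keys()].
#' @return list with character vectors `core`, `unique_a`, `unique_b`.
#' @export
intersect_psms <- function(a, b,
                           key_profile = c("file", "scan", "charge", "peptide")) {
  ka <- unique(spectrum_keys(a, key_profile))
  kb <- unique(spectrum_keys(b, key_profile))
  list(core = intersect(ka, kb),
       unique_a = setdiff(ka, kb),
       unique_b = setdiff(kb, ka))
}

#' Read a FASTA database
#'
#' Reads protein sequences via Biostrings and tags each entry's origin from
#' its accession prefix: `DECOY_` + `RND_` marks a reversed random sequence,
#' `DECOY_` a decoy of a real protein, `RND_` a random (entrapment)
#' sequence, anything else a real protein.
#'
#' @param path FASTA file path.
#' @param decoy_prefix,random_prefix accession prefixes.
#' @return data.frame with columns `accession`, `description`, `sequence`,
#'   `origin`.
#' @export
read_fasta <- function(path, decoy_prefix = "DECOY_", random_prefix = "RND_") {
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  accession <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  widths <- Biostrings::width(seqs)
  if (any(widths == 0L)) {
    stop("empty sequence under header(s): ",
         paste(accession[widths == 0L], collapse = ", "), call. = FALSE)
  }
  data.frame(accession = accession, description = description,
             sequence = as.character(seqs),
             origin = fasta_origin(accession, decoy_prefix, random_prefix),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Infer entry origin from an accession
#'
#' @param accession character vector of accessions.
#' @param decoy_prefix,random_prefix accession prefixes.
#' @return character vector among `real`, `random`, `decoy`, `random_decoy`.
#' @export
fasta_origin <- function(accession, decoy_prefix = "DECOY_",
                         random_prefix = "RND_") {
  ifelse(startsWith(accession, paste0(decoy_prefix, random_prefix)),
         "random_decoy",
  ifelse(startsWith(accession, decoy_prefix), "decoy",
  ifelse(startsWith(accession, random_prefix), "random", "real")))
}

#' Write a FASTA database
#'
#' @param entries data.frame with `accession`, `description`, `sequence`.
#' @param path output path.
#' @param width line-wrapping width (default 60 columns).
#' @export
write_fasta <- function(entries, path, width = 60L) {
  seqs <- Biostrings::AAStringSet(entries$sequence)
  names(seqs) <- ifelse(nzchar(entries$description),
                        paste(entries$accession, entries$description),
                        entries$accession)
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}
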