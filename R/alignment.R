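#' Aligned mitochondrial sequences with sample metadata
#'
#' A `coal_alignment` couples an equal-length nucleotide alignment with
#' per-sample metadata: population label, coordinates, and sample age in
#' generations before present (0 = modern; ancient samples enter the
#' coalescent at their age). The same container is used for observed and
#' simulated data so every statistic runs through one code path.
#'
#' @param seqs character matrix (samples x sites) of nucleotide states;
#'   rownames are sample ids. Gap (`-`), `N` and IUPAC ambiguity codes are
#'   permitted before trimming only.
#' @param meta data frame with columns `id`, `population`, `lon`, `lat`,
#'   `age_generations`; one row per sequence, matched by `id`.
#' @param validated internal flag to skip re-validation.
#' @return An object of class `coal_alignment` with fields `seqs` (character
#'   matrix) and `meta` (tibble).
#' @export
coal_alignment <- function(seqs, meta, validated = FALSE) {
  meta <- as_tibble(meta)
  need <- c("id", "population", "lon", "lat", "age_generations")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols)) {
    abort(paste0("metadata lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (is.null(rownames(seqs))) rownames(seqs) <- meta$id
  obj <- structure(list(seqs = seqs, meta = meta), class = "coal_alignment")
  if (!validated) validate_alignment(obj)
  obj
}

validate_alignment <- function(x) {
  seqs <- x$seqs
  meta <- x$meta
  if (ncol(seqs) < 1L) abort("alignment length must be >= 1")
  unmatched <- setdiff(rownames(seqs), meta$id)
  if (length(unmatched)) {
    abort(paste0("metadata error: no metadata row for id(s): ",
                 paste(unmatched, collapse = ", ")))
  }
  extra <- setdiff(meta$id, rownames(seqs))
  if (length(extra)) {
    abort(paste0("metadata error: metadata id(s) absent from alignment: ",
                 paste(extra, collapse = ", ")))
  }
  if (any(is.na(meta$population) | meta$population == "")) {
    abort("every sample must carry a population label")
  }
  if (any(meta$age_generations < 0)) abort("sample ages must be non-negative")
  ages <- tapply(meta$age_generations, meta$population, function(a) length(unique(a)))
  if (any(ages > 1L)) {
    abort(paste0("all samples within a population must share one sampling age; offending: ",
                 paste(names(ages)[ages > 1L], collapse = ", ")))
  }
  invisible(x)
}

#' @export
print.coal_alignment <- function(x, ...) {
  cat("<coal_alignment> ", nrow(x$seqs), " samples x ", ncol(x$seqs), " bp; ",
      length(unique(x$meta$population)), " population(s)\n", sep = "")
  invisible(x)
}

#' Number of samples / alignment length
#' @param x a `coal_alignment`.
#' @return integer.
#' @export
n_samples <- function(x) nrow(x$seqs)

#' @rdname n_samples
#' @export
alignment_length <- function(x) ncol(x$seqs)

#' Read an aligned FASTA plus a metadata table
#'
#' FASTA records and metadata rows are matched 1:1 by sequence id. All
#' sequences must have equal length (the input is assumed pre-aligned;
#' de novo alignment is out of scope).
#'
#' @param fasta_path path to an aligned FASTA file.
#' @param metadata_path path to a TSV with columns
#'   `id, population, lon, lat, age_generations`.
#' @return A [coal_alignment()].
#' @export
read_alignment <- function(fasta_path, metadata_path) {
  dna <- ape::read.FASTA(fasta_path)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L) {
    abort(paste0("alignment error: unequal sequence lengths (",
                 paste(range(lens), collapse = "-"), " bp)"))
  }
  seqs <- toupper(as.character(as.matrix(dna)))
  meta <- as_tibble(utils::read.delim(metadata_path, sep = "\t",
                                      stringsAsFactors = FALSE))
  absent <- setdiff(rownames(seqs), meta$id)
  if (length(absent)) {
    abort(paste0("metadata error: no metadata row for id(s): ",
                 paste(absent, collapse = ", ")))
  }
  meta <- meta[match(rownames(seqs), meta$id), , drop = FALSE]
  unlabeled <- is.na(meta$population) | meta$population == ""
  if (any(unlabeled)) {
    warn(paste0("dropping ", sum(unlabeled),
                " sample(s) with missing population label: ",
                paste(meta$id[unlabeled], collapse = ", ")))
    meta <- meta[!unlabeled, , drop = FALSE]
    seqs <- seqs[meta$id, , drop = FALSE]
  }
  coal_alignment(seqs, meta)
}

#' Write an alignment as FASTA + metadata TSV
#'
#' @param x a `coal_alignment`.
#' @param fasta_path,metadata_path output paths.
#' @return `x`, invisibly.
#' @export
write_alignment <- function(x, fasta_path, metadata_path = NULL) {
  dna <- ape::as.DNAbin(apply(x$seqs, 1L, paste0, collapse = "") |>
                          strsplit("") |> setNames(rownames(x$seqs)))
  ape::write.FASTA(dna, fasta_path)
  if (!is.null(metadata_path)) {
    utils::write.table(x$meta, metadata_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(x)
}

#' Trim an alignment to its maximal clean common region
#'
#' Finds the longest contiguous block of columns containing no gap (`-`),
#' `N` or `?` in any sequence, the convention used to remove low-quality
#' read ends and indels before simulation-based inference (coalescent
#' simulators do not model indel mutations). Sequences still containing
#' IUPAC ambiguity codes inside the retained block are dropped with a
#' warning rather than imputed.
#'
#' @param x a `coal_alignment`, possibly containing gaps/ambiguities.
#' @return A trimmed `coal_alignment` whose states are all in A/C/G/T, with
#'   attributes `trim_start`, `trim_end`, `trimmed_length` and
#'   `dropped_samples`.
#' @export
trim_alignment <- function(x) {
  seqs <- toupper(x$seqs)
  missing_state <- seqs %in% c("-", "N", "?")
  dim(missing_state) <- dim(seqs)
  clean_col <- !apply(missing_state, 2L, any)
  if (!any(clean_col)) abort("empty-region error: no gap-free column block")
  # longest run of clean columns (first such run on ties)
  r <- rle(clean_col)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  best <- cand[which.max(r$lengths[cand])]
  block <- starts[best]:ends[best]
  out <- seqs[, block, drop = FALSE]
  ambiguous <- apply(matrix(!(out %in% nucleotides), nrow = nrow(out)), 1L, any)
  if (any(ambiguous)) {
    warn(paste0("dropping ", sum(ambiguous),
                " sequence(s) with ambiguity codes inside the common block: ",
                paste(rownames(out)[ambiguous], collapse = ", ")))
  }
  out <- out[!ambiguous, , drop = FALSE]
  if (nrow(out) == 0L) abort("empty-region error: all sequences dropped")
  meta <- x$meta[match(rownames(out), x$meta$id), , drop = FALSE]
  res <- coal_alignment(out, meta)
  attr(res, "trim_start") <- block[1L]
  attr(res, "trim_end") <- block[length(block)]
  attr(res, "trimmed_length") <- length(block)
  attr(res, "dropped_samples") <- rownames(seqs)[ambiguous]
  res
}
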