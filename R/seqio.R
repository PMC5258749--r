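#' Read a FASTA file into a sequence tibble
#'
#' Sequences are returned in file order with residues uppercased. The
#' accepted alphabet is `A C G T U N`; any other character is an error that
#' reports the record and position. A record may use `T` or `U` but never
#' both.
#'
#' @param path Path to a FASTA file.
#' @param alphabet One of `"auto"` (keep residues as read), `"rna"`
#'   (convert `T` to `U`) or `"dna"` (convert `U` to `T`).
#' @return A tibble with columns `id`, `description`, `residues`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">x some description", "acgu"), f)
#' read_fasta(f)
read_fasta <- function(path, alphabet = c("auto", "rna", "dna")) {
  alphabet <- match.arg(alphabet)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) {
    stop("not a FASTA file (first line does not start with '>'): ", path,
         call. = FALSE)
  }
  rec <- cumsum(is_hdr)
  headers <- sub("^>", "", lines[is_hdr])
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  residues <- vapply(split(lines[!is_hdr], rec[!is_hdr]),
                     paste0, character(1), collapse = "")
  # headers with no sequence lines
  if (length(residues) < length(id)) {
    got <- as.integer(names(residues))
    full <- character(length(id))
    full[got] <- residues
    residues <- full
  }
  residues <- toupper(unname(residues))
  if (any(!nzchar(residues))) {
    stop("record without residues: ",
         paste(id[!nzchar(residues)], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(id)) {
    stop("duplicate sequence id: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  bad <- stringr::str_locate(residues, "[^ACGTUN]")[, "start"]
  if (any(!is.na(bad))) {
    k <- which(!is.na(bad))[1]
    stop("non-IUPAC character in record '", id[k], "' at position ", bad[k],
         call. = FALSE)
  }
  mixed <- grepl("T", residues, fixed = TRUE) & grepl("U", residues, fixed = TRUE)
  if (any(mixed)) {
    stop("record mixes T and U: ", paste(id[mixed], collapse = ", "),
         call. = FALSE)
  }
  residues <- switch(alphabet,
    auto = residues,
    rna  = gsub("T", "U", residues, fixed = TRUE),
    dna  = gsub("U", "T", residues, fixed = TRUE))
  tibble::tibble(id = id, description = description, residues = residues)
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Tibble with columns `id`, `residues` and optionally
#'   `description`.
#' @param path Output path.
#' @param width Line-wrap width for residues (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  desc <- if ("description" %in% names(seqs)) seqs$description else ""
  hdr <- ifelse(nzchar(desc), paste(seqs$id, desc), seqs$id)
  chunks <- purrr::map2(hdr, seqs$residues, function(h, s) {
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", h), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  })
  readr::write_lines(unlist(chunks), path)
  invisible(path)
}

#' Read small-RNA reads from FASTA or 4-line FASTQ
#'
#' The format is auto-detected from the first byte (`@` means FASTQ,
#' `>` means FASTA). FASTQ quality lines are discarded; reads are assumed to
#' be adapter-trimmed already.
#'
#' @param path Path to a FASTA or FASTQ file.
#' @return A tibble with columns `id`, `description`, `residues`.
#' @export
read_reads <- function(path) {
  first <- substr(readr::read_lines(path, n_max = 1L), 1, 1)
  if (length(first) == 0L) stop("empty reads file: ", path, call. = FALSE)
  if (first == ">") return(read_fasta(path))
  if (first != "@") {
    stop("unrecognized reads format (expected '@' or '>'): ", path,
         call. = FALSE)
  }
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ record at record index ",
         length(lines) %/% 4L + 1L, call. = FALSE)
  }
  idx <- seq(1L, length(lines), by = 4L)
  plus_ok <- startsWith(lines[idx + 2L], "+")
  if (!all(plus_ok)) {
    stop("malformed FASTQ record at record index ", which(!plus_ok)[1],
         call. = FALSE)
  }
  headers <- sub("^@", "", lines[idx])
  tibble::tibble(
    id = sub("\\s.*$", "", headers),
    description = ifelse(grepl("\\s", headers),
                         sub("^\\S+\\s+", "", headers), ""),
    residues = toupper(lines[idx + 1L])
  )
}

#' Merge overlapping intervals on one sequence
#'
#' Intervals are 1-based and fully closed. Strand is ignored: the merged,
#' disjoint set and the total number of covered positions are computed on
#' the sequence axis alone (as used for repeat coverage of precursors).
#'
#' @param intervals Tibble with columns `seq_id`, `start`, `end` (a `strand`
#'   column is allowed and ignored). All rows must share one `seq_id`.
#' @return A list with `intervals` (merged, sorted tibble) and `covered`
#'   (total covered length).
#' @export
#' @examples
#' merge_intervals(tibble::tibble(seq_id = "c", start = c(1, 21), end = c(30, 60)))
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0L) {
    return(list(intervals = tibble::tibble(seq_id = character(),
                                           start = integer(), end = integer()),
                covered = 0L))
  }
  if (length(unique(intervals$seq_id)) != 1L) {
    stop("merge_intervals() requires a single seq_id; got: ",
         paste(unique(intervals$seq_id), collapse = ", "), call. = FALSE)
  }
  stopifnot(all(intervals$start >= 1L), all(intervals$end >= intervals$start))
  iv <- dplyr::arrange(intervals, .data$start, .data$end)
  start <- iv$start; end <- iv$end
  keep_start <- integer(0); keep_end <- integer(0)
  cs <- start[1]; ce <- end[1]
  for (k in seq_len(nrow(iv))[-1]) {
    if (start[k] <= ce) { # overlap; adjacent intervals stay separate
      ce <- max(ce, end[k])
    } else {
      keep_start <- c(keep_start, cs); keep_end <- c(keep_end, ce)
      cs <- start[k]; ce <- end[k]
    }
  }
  keep_start <- c(keep_start, cs); keep_end <- c(keep_end, ce)
  out <- tibble::tibble(seq_id = iv$seq_id[1],
                        start = as.integer(keep_start),
                        end = as.integer(keep_end))
  list(intervals = out, covered = sum(out$end - out$start + 1L))
}

#' Reverse complement (RNA alphabet)
#'
#' Accepts RNA or DNA input; the result is always in the RNA alphabet
#' (the package's internal canonical alphabet). `N` maps to `N`.
#'
#' @param x Character vector of sequences.
#' @return Reverse-complemented RNA sequences.
#' @export
revcomp <- function(x) {
  chartr("ACGTUN", "UGCAAN", x) |>
    vapply(function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                             collapse = ""), character(1), USE.NAMES = FALSE)
}

#' Convert sequences to the RNA alphabet
#' @param x Character vector of sequences.
#' @return `x` with `T` replaced by `U`.
#' @export
as_rna <- function(x) gsub("T", "U", toupper(x), fixed = TRUE)

#' Convert sequences to the DNA alphabet
#' @param x Character vector of sequences.
#' @return `x` with `U` replaced by `T`.
#' @export
as_dna <- function(x) gsub("U", "T", toupper(x), fixed = TRUE)
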