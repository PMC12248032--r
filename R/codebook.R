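#' Combinatorial readout codebooks
#'
#' A codebook maps each targeted receptor to a unique constant-weight binary
#' barcode: a set of `on_bits` readout rounds (default 4) out of `n_bits`
#' (default 15) in which that receptor's probes fluoresce. Exact lookup of a
#' decoded bit set against the codebook is what turns image-level signal into
#' a receptor identity, so uniqueness and determinism are enforced here.
#'
#' @name codebook
NULL

new_codebook <- function(entries, n_bits, on_bits, blanks = NULL) {
  structure(
    list(entries = entries, n_bits = as.integer(n_bits),
         on_bits = as.integer(on_bits), blanks = blanks),
    class = "or_codebook"
  )
}

#' Build a combinatorial codebook
#'
#' Assigns each receptor a unique set of `on_bits` bit indices out of
#' `n_bits`. All constant-weight codes are enumerated lexicographically,
#' shuffled with `seed`, and assigned to receptors in input order, so the
#' assignment is deterministic given the seed.
#'
#' @param receptor_ids Character vector of unique receptor identifiers.
#' @param n_bits Total number of readout bits (default 15).
#' @param on_bits Number of on-bits per code (default 4).
#' @param seed Integer seed fixing the assignment permutation.
#' @param n_blanks Number of unused codes to reserve as blanks for error
#'   estimation (default 0; blanks count against capacity).
#' @return An object of class `or_codebook` with an integer matrix `entries`
#'   (one row per receptor, 0-based bit indices sorted ascending).
#' @examples
#' cb <- build_codebook(c("Olfr1", "Olfr2"), n_bits = 15, on_bits = 4, seed = 1)
#' cb$entries
#' @export
build_codebook <- function(receptor_ids, n_bits = 15L, on_bits = 4L,
                           seed = 1L, n_blanks = 0L) {
  receptor_ids <- as.character(receptor_ids)
  if (anyDuplicated(receptor_ids))
    stop_orfish("duplicate receptor ids", class = "orfish_input_error")
  n_bits <- as.integer(n_bits); on_bits <- as.integer(on_bits)
  if (on_bits < 1L || on_bits > n_bits)
    stop_orfish("on_bits must be in [1, n_bits]", class = "orfish_input_error")
  capacity <- choose(n_bits, on_bits)
  n_needed <- length(receptor_ids) + n_blanks
  if (n_needed > capacity)
    stop_orfish(sprintf(
      "capacity exceeded: %d codes requested but only %d distinct %d-of-%d codes exist",
      n_needed, capacity, on_bits, n_bits), class = "orfish_capacity_error")
  # lexicographic enumeration of all on_bits-subsets, 0-based
  all_codes <- t(utils::combn(n_bits, on_bits)) - 1L
  perm <- with_seed(seed, sample.int(nrow(all_codes)))
  chosen <- all_codes[perm[seq_len(n_needed)], , drop = FALSE]
  entries <- chosen[seq_along(receptor_ids), , drop = FALSE]
  rownames(entries) <- receptor_ids
  colnames(entries) <- paste0("bit_", seq_len(on_bits) - 1L)
  blanks <- NULL
  if (n_blanks > 0L) {
    blanks <- chosen[length(receptor_ids) + seq_len(n_blanks), , drop = FALSE]
    rownames(blanks) <- paste0("blank_", seq_len(n_blanks))
    colnames(blanks) <- colnames(entries)
  }
  new_codebook(entries, n_bits, on_bits, blanks)
}

#' @export
print.or_codebook <- function(x, ...) {
  cat(sprintf("or_codebook: %d receptors, %d-of-%d codes, %d blank(s)\n",
              nrow(x$entries), x$on_bits, x$n_bits,
              if (is.null(x$blanks)) 0L else nrow(x$blanks)))
  invisible(x)
}

#' Look up the receptor carrying a bit set
#'
#' @param codebook An `or_codebook`.
#' @param bits Integer vector of bit indices (any order).
#' @return The receptor id, or `NA_character_` if the code is not in the book.
#' @export
receptor_for_code <- function(codebook, bits) {
  keys <- apply(codebook$entries, 1L, bit_key)
  idx <- match(bit_key(bits), keys)
  if (is.na(idx)) NA_character_ else rownames(codebook$entries)[idx]
}

#' Validate a codebook
#'
#' Reports duplicate codes and the minimum pairwise Hamming distance over all
#' code pairs (receptors plus any reserved blanks). Constant-weight codes have
#' even pairwise distances, so a valid book has minimum distance at least 2.
#'
#' @param codebook An `or_codebook`.
#' @return A list with `duplicates` (character vector of receptor ids sharing
#'   a code with an earlier entry, empty when valid), `min_hamming`, and the
#'   full `hamming` distance matrix.
#' @export
validate_codebook <- function(codebook) {
  codes <- rbind(codebook$entries, codebook$blanks)
  n <- nrow(codes)
  B <- matrix(0L, n, codebook$n_bits)
  B[cbind(rep(seq_len(n), each = codebook$on_bits), as.integer(t(codes)) + 1L)] <- 1L
  H <- 2L * codebook$on_bits - 2L * tcrossprod(B)
  dimnames(H) <- list(rownames(codes), rownames(codes))
  keys <- apply(codes, 1L, bit_key)
  dup <- rownames(codes)[duplicated(keys)]
  off <- H[upper.tri(H)]
  list(duplicates = dup,
       min_hamming = if (length(off)) as.integer(min(off)) else NA_integer_,
       hamming = H)
}

#' Assemble split-probe records for a codebook
#'
#' Each receptor transcript is tiled by adjacent probe pairs; each pair
#' carries one of the receptor's code bits through a 15-nt 5' / 15-nt 3'
#' split readout flanking a 30-32 nt target region, and each bit is repeated
#' `repeats_per_bit` times (4-10) along the transcript. Nucleotide sequences
#' themselves are not generated; records carry layout metadata only.
#'
#' @param codebook An `or_codebook`.
#' @param target_intervals Named list (one element per receptor) of two-column
#'   integer matrices of half-open, 0-based `[start, end)` intervals on the
#'   transcript, each 30-32 nt long and mutually non-overlapping; at least
#'   `on_bits * repeats_per_bit` intervals per receptor.
#' @param repeats_per_bit Repeats of each bit per transcript, in `[4, 10]`.
#' @return A data.frame of probe records: `receptor_id`, `bit_index`,
#'   `repeat_index`, `target_start`, `target_end`, and fixed layout lengths
#'   (`fwd_primer_nt`, `rt_primer_nt`, `split5_nt`, `split3_nt`,
#'   `rev_primer_nt`).
#' @export
assemble_probe_records <- function(codebook, target_intervals, repeats_per_bit = 4L) {
  repeats_per_bit <- as.integer(repeats_per_bit)
  if (repeats_per_bit < 4L || repeats_per_bit > 10L)
    stop_orfish("repeats_per_bit must be in [4, 10]", class = "orfish_layout_error")
  ids <- rownames(codebook$entries)
  missing <- setdiff(ids, names(target_intervals))
  if (length(missing))
    stop_orfish("no target intervals for: ", paste(missing, collapse = ", "),
                class = "orfish_input_error")
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    iv <- target_intervals[[id]]
    iv <- matrix(as.integer(iv), ncol = 2L)
    len <- iv[, 2L] - iv[, 1L]
    if (any(len < 30L | len > 32L))
      stop_orfish(id, ": target interval length outside [30, 32] nt",
                  class = "orfish_layout_error")
    o <- order(iv[, 1L])
    iv <- iv[o, , drop = FALSE]
    if (nrow(iv) > 1L && any(iv[-1L, 1L] < iv[-nrow(iv), 2L]))
      stop_orfish(id, ": overlapping target intervals",
                  class = "orfish_layout_error")
    need <- codebook$on_bits * repeats_per_bit
    if (nrow(iv) < need)
      stop_orfish(id, sprintf(": %d intervals supplied, %d required",
                              nrow(iv), need), class = "orfish_layout_error")
    bits <- rep(codebook$entries[i, ], each = repeats_per_bit)
    reps <- rep(seq_len(repeats_per_bit), times = codebook$on_bits)
    out[[i]] <- data.frame(
      receptor_id = id,
      bit_index = as.integer(bits),
      repeat_index = reps,
      target_start = iv[seq_len(need), 1L],
      target_end = iv[seq_len(need), 2L],
      stringsAsFactors = FALSE
    )
  }
  rec <- do.call(rbind, out)
  rownames(rec) <- NULL
  rec$fwd_primer_nt <- 20L
  rec$rt_primer_nt <- 20L
  rec$split5_nt <- 15L
  rec$split3_nt <- 15L
  rec$rev_primer_nt <- 20L
  rec
}

#' Tile non-overlapping target intervals along a transcript
#'
#' Convenience generator of `n` half-open intervals of length 30-32 nt with a
#' fixed inter-probe gap, for building probe records.
#'
#' @param transcript_length Length of the transcript in nt.
#' @param n Number of intervals.
#' @param lengths Allowed interval lengths (default `30:32`, cycled).
#' @param gap Gap between consecutive intervals in nt.
#' @return A two-column integer matrix of `[start, end)` intervals.
#' @export
tile_target_intervals <- function(transcript_length, n, lengths = 30:32, gap = 2L) {
  len <- rep_len(as.integer(lengths), n)
  start <- cumsum(c(0L, len[-n] + gap))
  end <- start + len
  if (n > 0 && end[n] > transcript_length)
    stop_orfish("transcript too short for requested tiling",
                class = "orfish_layout_error")
  cbind(start = start, end = end)
}

#' Write / read a codebook as CSV
#'
#' The CSV has columns `receptor_id, bit_0, ..., bit_k`; blanks are stored
#' with ids prefixed `blank_`. The round trip is lossless.
#'
#' @param codebook An `or_codebook`.
#' @param path File path.
#' @return `write_codebook` returns `path` invisibly; `read_codebook` returns
#'   an `or_codebook`.
#' @export
write_codebook <- function(codebook, path) {
  codes <- rbind(codebook$entries, codebook$blanks)
  df <- data.frame(receptor_id = rownames(codes), codes,
                   n_bits = codebook$n_bits, row.names = NULL,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  bit_cols <- grep("^bit_", names(df), value = TRUE)
  codes <- as.matrix(df[, bit_cols, drop = FALSE])
  storage.mode(codes) <- "integer"
  rownames(codes) <- df$receptor_id
  is_blank <- grepl("^blank_", df$receptor_id)
  new_codebook(codes[!is_blank, , drop = FALSE],
               n_bits = df$n_bits[1L], on_bits = ncol(codes),
               blanks = if (any(is_blank)) codes[is_blank, , drop = FALSE] else NULL)
}
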