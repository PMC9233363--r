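#' Generate a random circular mitochondrial-like reference sequence
#'
#' Draws a sequence of independent bases with a specified GC content,
#' standing in for a circular mitochondrial genome (the human reference is
#' 16,569 bp with roughly 44% GC). The sequence is treated as circular by
#' all downstream context calls: position `length` is followed by position 1.
#'
#' @param length Number of bases (>= 100).
#' @param gc_fraction Target GC fraction, strictly between 0 and 1.
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @return A single uppercase character string over `{A,C,G,T}`.
#' @examples
#' ref <- generate_reference(200, 0.44, seed = 1)
#' nchar(ref)
#' @export
generate_reference <- function(length, gc_fraction = 0.44, seed = 1L) {
  assert_scalar_number(length, "length")
  assert_scalar_number(gc_fraction, "gc_fraction")
  if (length < 100) {
    rlang::abort("`length` must be at least 100 bases to place planted sites.")
  }
  if (gc_fraction <= 0 || gc_fraction >= 1) {
    rlang::abort("`gc_fraction` must be strictly between 0 and 1.")
  }
  probs <- c(
    A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
    G = gc_fraction / 2, T = (1 - gc_fraction) / 2
  )
  bases <- with_seed(seed, sample(names(probs), length, replace = TRUE, prob = probs))
  paste(bases, collapse = "")
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# 1-based circular index into a genome of length n.
wrap_position <- function(pos, n) {
  ((pos - 1L) %% n) + 1L
}

#' Classify the sequence context of a cytosine
#'
#' Determines whether a cytosine sits in a CpG, CHG, or CHH context (H being
#' A, C, or T) by inspecting the two bases immediately downstream on the
#' cytosine's own strand, with circular wraparound. On the heavy (H, `+`)
#' strand the reference is read as-is; on the light (L, `-`) strand the
#' reverse complement is consulted, so a light-strand cytosine corresponds to
#' a `G` in the reference and its downstream neighbours lie at decreasing
#' reference positions.
#'
#' @param reference Reference sequence as a single character string.
#' @param position 1-based position(s) on the reference; vectorised.
#' @param strand `"+"` (H-chain) or `"-"` (L-chain); recycled to match
#'   `position`.
#' @return Character vector of `"CpG"`, `"CHG"`, or `"CHH"`.
#' @examples
#' classify_context("ACGAT", 2, "+") # CpG
#' @export
classify_context <- function(reference, position, strand) {
  chars <- strsplit(toupper(reference), "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (any(position < 1 | position > n)) {
    rlang::abort("`position` out of range for the reference.")
  }
  if (length(strand) == 1L) strand <- rep(strand, length(position))
  if (!all(strand %in% c("+", "-"))) {
    rlang::abort('`strand` must be "+" (H) or "-" (L).')
  }
  plus <- strand == "+"
  base <- chars[position]
  bad <- (plus & base != "C") | (!plus & base != "G")
  if (any(bad)) {
    rlang::abort(sprintf(
      "No cytosine at position(s) %s on the requested strand.",
      paste(position[bad][seq_len(min(5, sum(bad)))], collapse = ", ")
    ))
  }
  n1 <- n2 <- character(length(position))
  n1[plus] <- chars[wrap_position(position[plus] + 1L, n)]
  n2[plus] <- chars[wrap_position(position[plus] + 2L, n)]
  n1[!plus] <- unname(COMPLEMENT[chars[wrap_position(position[!plus] - 1L, n)]])
  n2[!plus] <- unname(COMPLEMENT[chars[wrap_position(position[!plus] - 2L, n)]])
  dplyr::case_when(n1 == "G" ~ "CpG", n2 == "G" ~ "CHG", TRUE ~ "CHH")
}

# Trinucleotide (cytosine + two downstream bases) on the cytosine's strand.
trinucleotide_at <- function(reference, position, strand) {
  chars <- strsplit(toupper(reference), "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (length(strand) == 1L) strand <- rep(strand, length(position))
  plus <- strand == "+"
  out <- character(length(position))
  out[plus] <- paste0(
    chars[position[plus]],
    chars[wrap_position(position[plus] + 1L, n)],
    chars[wrap_position(position[plus] + 2L, n)]
  )
  out[!plus] <- paste0(
    unname(COMPLEMENT[chars[position[!plus]]]),
    unname(COMPLEMENT[chars[wrap_position(position[!plus] - 1L, n)]]),
    unname(COMPLEMENT[chars[wrap_position(position[!plus] - 2L, n)]])
  )
  out
}

#' Enumerate every cytosine on both strands of a circular reference
#'
#' @param reference Reference sequence as a single character string.
#' @return A tibble with `position`, `strand` (`+` = H-chain, `-` = L-chain),
#'   `context`, and `trinucleotide`, sorted by position then strand.
#' @export
all_cytosines <- function(reference) {
  chars <- strsplit(toupper(reference), "", fixed = TRUE)[[1]]
  pos_h <- which(chars == "C")
  pos_l <- which(chars == "G")
  out <- tibble::tibble(
    position = c(pos_h, pos_l),
    strand = c(rep("+", length(pos_h)), rep("-", length(pos_l)))
  )
  out <- dplyr::arrange(out, .data$position, .data$strand)
  out$context <- classify_context(reference, out$position, out$strand)
  out$trinucleotide <- trinucleotide_at(reference, out$position, out$strand)
  out
}
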