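#' Parse a DNA duplex from a sequence string
#'
#' A duplex is an ordered run of base-pair classes, AT or GC, indexed
#' 1-based in the 5' to 3' direction of the given strand. Two input
#' alphabets are supported: \code{"shorthand"}, where \code{G} denotes a
#' GC/CG pair and \code{A} an AT/TA pair (the notation used for the 8-bp
#' duplexes GGGAGAAG "chain-A" and GGAAGAGG "chain-B"), and
#' \code{"literal"}, where any of G/C maps to a GC pair and any of A/T to
#' an AT pair.
#'
#' @param text non-empty sequence string (case-insensitive).
#' @param alphabet \code{"shorthand"} (letters G, A) or \code{"literal"}
#'   (letters G, C, A, T).
#' @param label free-text label carried through to outputs.
#' @return An object of class \code{pbd_duplex}: list with \code{pairs}
#'   (character vector of "AT"/"GC"), \code{n}, \code{label}.
#' @examples
#' chainA <- parse_duplex("GGGAGAAG")
#' chainA$pairs   # GC GC GC AT GC AT AT GC
#' parse_duplex("GCCATT", alphabet = "literal")$pairs
#' @export
parse_duplex <- function(text, alphabet = c("shorthand", "literal"),
                         label = text) {
  alphabet <- match.arg(alphabet)
  if (!is.character(text) || length(text) != 1L || !nzchar(text)) {
    stop("sequence must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(toupper(text), "")[[1]]
  map <- if (alphabet == "shorthand") {
    c(G = "GC", A = "AT")
  } else {
    c(G = "GC", C = "GC", A = "AT", T = "AT")
  }
  bad <- which(!(chars %in% names(map)))
  if (length(bad) > 0) {
    stop(sprintf("unknown character '%s' at position %d (alphabet '%s')",
                 chars[bad[1]], bad[1], alphabet), call. = FALSE)
  }
  new_duplex(unname(map[chars]), label = label)
}

new_duplex <- function(pairs, label = "") {
  stopifnot(length(pairs) >= 1L, all(pairs %in% c("AT", "GC")))
  structure(list(pairs = pairs, n = length(pairs), label = label),
            class = "pbd_duplex")
}

#' Format a duplex back to its shorthand string
#'
#' Inverse of [parse_duplex()] under the shorthand alphabet: GC pairs print
#' as \code{G}, AT pairs as \code{A}.
#'
#' @param duplex a \code{pbd_duplex}.
#' @return Single string.
#' @export
format_duplex <- function(duplex) {
  paste(ifelse(duplex$pairs == "GC", "G", "A"), collapse = "")
}

#' @export
print.pbd_duplex <- function(x, ...) {
  cat(sprintf("PBD duplex '%s': %d bp (%d GC, %d AT)\n  %s\n",
              x$label, x$n, sum(x$pairs == "GC"), sum(x$pairs == "AT"),
              format_duplex(x)))
  invisible(x)
}

#' Read a duplex from a single-record FASTA file
#'
#' Reads the first (and only) record of a FASTA file and parses it with
#' [parse_duplex()]. Requires the Biostrings package.
#'
#' @param path FASTA file path.
#' @param alphabet passed to [parse_duplex()].
#' @return A \code{pbd_duplex}; the record name becomes the label.
#' @export
read_duplex_fasta <- function(path, alphabet = c("shorthand", "literal")) {
  alphabet <- match.arg(alphabet)
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package", call. = FALSE)
  }
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no FASTA record in ", path, call. = FALSE)
  if (length(ss) > 1L) {
    warning("multiple FASTA records in ", path, "; using the first")
  }
  parse_duplex(as.character(ss[[1]]), alphabet = alphabet,
               label = names(ss)[1])
}

#' Generate a random heteropolymer duplex
#'
#' Draws a sequence with an exact GC count of \code{floor(n * gc_fraction)}
#' placed uniformly at random (sampling site indices without replacement),
#' so the realised GC fraction is deterministic given \code{n} and
#' \code{gc_fraction}. Used to stand in for the unpublished long-chain
#' sequences in the 50/100/300-bp crowding scenarios.
#'
#' @param n chain length (base pairs).
#' @param gc_fraction target GC proportion in [0, 1].
#' @param seed integer seed; the same seed always yields the same sequence.
#' @param label label for the duplex.
#' @return A \code{pbd_duplex}.
#' @examples
#' d <- generate_random_duplex(50, 0.5, seed = 1)
#' sum(d$pairs == "GC")  # exactly 25
#' @export
generate_random_duplex <- function(n, gc_fraction = 0.5, seed,
                                   label = sprintf("random-%dbp", n)) {
  if (!is.numeric(gc_fraction) || gc_fraction < 0 || gc_fraction > 1) {
    stop("gc_fraction must be in [0, 1]", call. = FALSE)
  }
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  n_gc <- floor(n * gc_fraction)
  pairs <- rep("AT", n)
  if (n_gc > 0) {
    gc_sites <- withr::with_seed(seed, sample.int(n, n_gc))
    pairs[gc_sites] <- "GC"
  }
  new_duplex(pairs, label = label)
}
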