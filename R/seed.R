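#' Construct a validated siRNA guide sequence
#'
#' Normalizes a raw guide (antisense) strand sequence into the RNA alphabet
#' read 5'->3'. Input may be in DNA or RNA alphabet and any case; whitespace
#' is stripped, letters are uppercased, and T is converted to U. The guide
#' must be at least 8 nt so that the canonical seed region (positions 2-8 of
#' the 5' end) exists.
#'
#' @param sequence Character scalar, the guide strand 5'->3' over
#'   \code{A,C,G,U} (or \code{T}, converted to \code{U}).
#' @param name Free-text label used to name match-count columns and plots.
#' @return An object of class \code{guide_sequence} with elements
#'   \code{sequence} (normalized RNA string) and \code{name}.
#' @examples
#' guide_sequence("uuAUAGAGCAAGAACACUGUUUU", name = "example")
#' @export
guide_sequence <- function(sequence, name = "guide") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("`sequence` must be a single character string")
  raw <- gsub("[[:space:]]", "", sequence)
  if (!nzchar(raw)) stop("guide sequence is empty")
  up <- toupper(raw)
  bad <- unique(strsplit(gsub("[ACGTU]", "", up), "")[[1]])
  if (length(bad))
    stop("invalid characters in guide sequence: ",
         paste(bad, collapse = ", "), " (alphabet is A, C, G, U/T)")
  rna <- chartr("T", "U", up)
  if (nchar(rna) < 8L)
    stop("guide sequence must be at least 8 nt (got ", nchar(rna),
         "); the seed region spans the first ~8 nt of the 5' end")
  structure(list(sequence = rna, name = as.character(name)[1]),
            class = "guide_sequence")
}

#' @export
print.guide_sequence <- function(x, ...) {
  cat("siRNA guide (", x$name, "): 5'-", x$sequence, "-3' [",
      nchar(x$sequence), " nt]\n", sep = "")
  invisible(x)
}

#' Built-in seed definitions
#'
#' The canonical miRNA-style seed site types, as windows on the guide strand
#' (1-based, position 1 = 5' nucleotide) plus whether an A is appended to the
#' 3' end of the DNA target pattern (modelling an adenine opposite guide
#' position 1 on the transcript).
#'
#' @return A data.frame with columns \code{name}, \code{start}, \code{stop},
#'   \code{append_a}. \code{mer7m8} is the package default.
#' @examples
#' seed_definitions()
#' @export
seed_definitions <- function() {
  data.frame(
    name = c("mer8", "mer7m8", "mer7A1", "mer6"),
    start = c(2L, 2L, 2L, 2L),
    stop = c(8L, 8L, 7L, 7L),
    append_a = c(TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

new_seed_definition <- function(name, start, stop, append_a) {
  start <- as.integer(start); stop <- as.integer(stop)
  if (is.na(start) || is.na(stop) || start < 1L || start > stop)
    stop("invalid seed window: need 1 <= start <= stop (got start=", start,
         ", stop=", stop, ")")
  structure(list(name = name, start = start, stop = stop,
                 append_a = isTRUE(append_a)),
            class = "seed_definition")
}

resolve_seed_definition <- function(seed) {
  if (inherits(seed, "seed_definition")) return(seed)
  defs <- seed_definitions()
  if (!is.character(seed) || length(seed) != 1L || !seed %in% defs$name)
    stop("unknown seed definition '", seed, "'; built-ins are: ",
         paste(defs$name, collapse = ", "),
         " (or use custom_seed() for an arbitrary window)")
  i <- match(seed, defs$name)
  new_seed_definition(defs$name[i], defs$start[i], defs$stop[i],
                      defs$append_a[i])
}

#' Derive the seed sequence and DNA target pattern for a guide
#'
#' Takes the seed window \code{[start, stop]} on the guide, and builds the
#' DNA pattern to search for on transcript features: the reverse complement
#' of the seed (U->T), with a trailing \code{A} appended when the definition
#' requires an adenine opposite guide position 1 (mer8, mer7A1).
#'
#' @param guide A \code{guide_sequence} (or a character string, normalized
#'   via [guide_sequence()]).
#' @param seed A built-in definition name (\code{"mer7m8"} (default),
#'   \code{"mer8"}, \code{"mer7A1"}, \code{"mer6"}) or a
#'   \code{seed_definition}.
#' @return A \code{seed_pattern}: list with \code{definition},
#'   \code{seed_rna} (guide subsequence), \code{target_dna} (search pattern)
#'   and \code{guide_name}.
#' @examples
#' g <- guide_sequence("UUAUAGAGCAAGAACACUGUUUU", "example")
#' get_seed(g, "mer7m8") # target CTCTATA
#' get_seed(g, "mer8")   # target CTCTATAA
#' @seealso [custom_seed()], [plot_seeds()]
#' @export
get_seed <- function(guide, seed = "mer7m8") {
  if (is.character(guide)) guide <- guide_sequence(guide)
  stopifnot(inherits(guide, "guide_sequence"))
  def <- resolve_seed_definition(seed)
  n <- nchar(guide$sequence)
  if (def$stop > n)
    stop("seed definition '", def$name, "' spans positions ", def$start, "-",
         def$stop, " but the guide is only ", n, " nt")
  seed_rna <- substr(guide$sequence, def$start, def$stop)
  core <- Biostrings::reverseComplement(
    Biostrings::DNAString(chartr("U", "T", seed_rna)))
  target <- paste0(as.character(core), if (def$append_a) "A" else "")
  structure(list(definition = def, seed_rna = seed_rna, target_dna = target,
                 guide_name = guide$name),
            class = "seed_pattern")
}

#' Derive a seed pattern from a custom window on the guide
#'
#' @inheritParams get_seed
#' @param start,stop 1-based inclusive guide positions (position 1 = 5' end).
#' @param append_a Append an \code{A} to the 3' end of the DNA target
#'   pattern (adenine opposite guide position 1).
#' @return A \code{seed_pattern} whose definition is named \code{"custom"}.
#' @examples
#' custom_seed("UUAUAGAGCAAGAACACUGUUUU", 2, 8) # identical to mer7m8
#' @export
custom_seed <- function(guide, start, stop, append_a = FALSE) {
  if (is.character(guide)) guide <- guide_sequence(guide)
  def <- new_seed_definition("custom", start, stop, append_a)
  if (def$stop > nchar(guide$sequence))
    stop("custom seed window ", def$start, "-", def$stop,
         " exceeds guide length ", nchar(guide$sequence))
  get_seed(guide, def)
}

#' @export
print.seed_pattern <- function(x, ...) {
  d <- x$definition
  cat("Seed pattern (", d$name, ", guide positions ", d$start, "-", d$stop,
      if (d$append_a) ", +A" else "", ")\n", sep = "")
  cat("  seed (RNA, 5'->3'):   ", x$seed_rna, "\n", sep = "")
  cat("  target (DNA, 5'->3'): ", x$target_dna, "\n", sep = "")
  invisible(x)
}

as_target_dna <- function(pattern) {
  if (inherits(pattern, "seed_pattern")) return(pattern$target_dna)
  if (is.character(pattern) && length(pattern) == 1L) return(toupper(pattern))
  stop("`pattern` must be a seed_pattern or a single DNA string")
}
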