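#' @useDynLib mitorho, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.mitorho_env <- new.env(parent = emptyenv())

#' Construct a mitochondrial reference genome object
#'
#' @param name identifier for the reference.
#' @param sequence nucleotide string (alphabet A, C, G, T, N).
#' @param circular logical; mitogenomes are circular.
#' @return An object of class `mt_reference` with fields `name`, `sequence`,
#'   `length`, `circular` and a pre-split character vector `chars`.
#' @export
mt_reference_genome <- function(name, sequence, circular = TRUE) {
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L)
    stop("reference alphabet restricted to A,C,G,T,N; found: ",
         paste(bad, collapse = ","))
  structure(
    list(name = name, sequence = sequence, length = length(chars),
         circular = isTRUE(circular), chars = chars),
    class = "mt_reference"
  )
}

#' Read a reference genome from a FASTA file
#'
#' @param path FASTA file with a single record.
#' @param circular logical, default `TRUE`.
#' @return An `mt_reference`.
#' @export
read_reference <- function(path, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L) stop("reference FASTA must contain exactly one record")
  mt_reference_genome(sub("\\s.*$", "", names(ss)[1L]),
                      as.character(ss[[1L]]), circular = circular)
}

#' The packaged rCRS-coordinate reference
#'
#' Returns the reference genome packaged with mitorho: a synthetic 16,569-bp
#' stand-in on rCRS coordinates. Positions used by the packaged haplogroup
#' tree carry the documented reference alleles (e.g. C64, T195, G8251, A9156,
#' C11288, G12771) and the unstable poly-C tracts around 303-315 and
#' 16183-16193 are present, so all nucleotide-position ("np") bookkeeping
#' behaves as it would on the true rCRS. The remaining bases are synthetic;
#' see the package vignette.
#'
#' @return An `mt_reference` of length 16,569, circular.
#' @export
mt_reference <- function() {
  if (is.null(.mitorho_env$rcrs)) {
    path <- system.file("extdata", "rCRS_synthetic.fasta", package = "mitorho",
                        mustWork = TRUE)
    ref <- read_reference(path)
    ref$name <- "rCRS_synthetic"
    .mitorho_env$rcrs <- ref
  }
  .mitorho_env$rcrs
}

#' @export
print.mt_reference <- function(x, ...) {
  cat(sprintf("<mt_reference> %s: %d bp, %s\n", x$name, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Default excluded-site mask
#'
#' Poly-C tract positions 303-315 and 16183-16194 plus 16519, the sites most
#' prone to length/point instability in human mtDNA phylogenetics. Calls at
#' these positions are suppressed and recorded as excluded.
#'
#' @return Integer vector of 1-based rCRS positions.
#' @export
default_mask <- function() {
  c(303:315, 16183:16194, 16519L)
}

#' Apply a set of variants to a reference sequence
#'
#' Substitutions replace the reference base, deletions remove it, insertions
#' add bases after their anchor position (ordered by insertion index). Used to
#' reconstruct haplotype sequences from rCRS-relative profiles.
#'
#' @param variants an `mt_variants` table (see [parse_variants()]).
#' @param ref an `mt_reference`; default the packaged reference.
#' @return The derived nucleotide sequence as a single string.
#' @export
apply_variants <- function(variants, ref = mt_reference()) {
  v <- as_mt_variants(variants, ref = ref)
  if (any(v$back))
    stop("back-mutation flags are only meaningful inside haplogroup ",
         "definitions; resolve them (cumulative_expected) before applying")
  if (nrow(v) > 0 && (min(v$position) < 1L || max(v$position) > ref$length))
    stop("variant position out of reference range")
  chars <- ref$chars
  ins <- vector("list", ref$length)
  keep <- rep(TRUE, ref$length)
  if (nrow(v) > 0) {
    for (i in seq_len(nrow(v))) {
      p <- v$position[i]
      switch(v$kind[i],
        sub = {
          if (!is.na(v$ref[i]) && v$ref[i] != "N" && chars[p] != v$ref[i])
            stop(sprintf("variant %s: reference has %s at %d",
                         v$token[i], chars[p], p))
          chars[p] <- v$alt[i]
        },
        del = keep[p] <- FALSE,
        ins = {
          cur <- ins[[p]]
          ins[[p]] <- c(cur, stats::setNames(v$alt[i], v$ins_index[i]))
        }
      )
    }
  }
  has_ins <- !vapply(ins, is.null, logical(1))
  if (!any(has_ins) && all(keep))        # substitution-only fast path
    return(paste0(chars, collapse = ""))
  pieces <- as.list(ifelse(keep, chars, ""))
  for (p in which(has_ins)) {
    o <- ins[[p]][order(as.integer(names(ins[[p]])))]
    pieces[[p]] <- paste0(pieces[[p]], paste0(o, collapse = ""))
  }
  paste0(unlist(pieces), collapse = "")
}
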