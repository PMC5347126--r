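# mtDNA variant nomenclature (PhyloTree dialect) and variant calling.
#
# Canonical tokens: substitutions "A9156G" (trailing "!" = back mutation),
# deletions "249d", insertions "315.1C". Positions are 1-based rCRS ("np").

.mt_variant_cols <- c("position", "kind", "ref", "alt", "ins_index",
                      "back", "token")

.empty_variants <- function() {
  structure(
    data.frame(position = integer(0), kind = character(0), ref = character(0),
               alt = character(0), ins_index = integer(0), back = logical(0),
               token = character(0), stringsAsFactors = FALSE),
    class = c("mt_variants", "data.frame")
  )
}

.make_variants <- function(position, kind, refa, alta, ins_index, back) {
  token <- .format_tokens(position, kind, refa, alta, ins_index, back)
  structure(
    data.frame(position = as.integer(position), kind = kind, ref = refa,
               alt = alta, ins_index = as.integer(ins_index), back = back,
               token = token, stringsAsFactors = FALSE),
    class = c("mt_variants", "data.frame")
  )
}

.format_tokens <- function(position, kind, refa, alta, ins_index, back) {
  out <- character(length(position))
  s <- kind == "sub"
  out[s] <- paste0(refa[s], position[s], alta[s], ifelse(back[s], "!", ""))
  d <- kind == "del"
  out[d] <- paste0(position[d], "d", ifelse(back[d], "!", ""))
  i <- kind == "ins"
  out[i] <- paste0(position[i], ".", ins_index[i], alta[i],
                   ifelse(back[i], "!", ""))
  out
}

#' Parse mtDNA variant nomenclature tokens
#'
#' Accepted dialects: `RefPosAlt` ("A9156G"), `PosAlt` ("9156G", reference
#' allele looked up), insertions `Pos.IdxBases` ("315.1C"), deletions `Posd`
#' ("249d"), each with an optional trailing `"!"` marking a back mutation
#' (meaningful only inside haplogroup definitions).
#'
#' @param tokens character vector of tokens.
#' @param ref `mt_reference` used to fill/validate reference alleles; `NULL`
#'   skips the lookup (then `PosAlt` tokens are rejected).
#' @return An `mt_variants` data frame with columns position, kind
#'   (`sub`/`ins`/`del`), ref, alt, ins_index, back, token (canonical form).
#' @export
parse_variants <- function(tokens, ref = mt_reference()) {
  if (length(tokens) == 0L) return(.empty_variants())
  tokens <- as.character(tokens)
  if (any(is.na(tokens) | tokens == ""))
    stop("empty variant token")
  raw <- tokens
  back <- grepl("!$", tokens)
  tokens <- sub("!$", "", tokens)

  n <- length(tokens)
  position <- integer(n); kind <- character(n)
  refa <- character(n); alta <- character(n); ins_index <- rep(NA_integer_, n)

  m_sub  <- regmatches(tokens, regexec("^([ACGT])([0-9]+)([ACGT])$", tokens))
  m_posa <- regmatches(tokens, regexec("^([0-9]+)([ACGT])$", tokens))
  m_ins  <- regmatches(tokens, regexec("^([0-9]+)\\.([0-9]+)([ACGT]+)$", tokens))
  m_del  <- regmatches(tokens, regexec("^([0-9]+)[dD]$", tokens))

  maxlen <- if (is.null(ref)) 16569L else ref$length
  for (i in seq_len(n)) {
    if (length(m_sub[[i]]) == 4L) {
      kind[i] <- "sub"
      refa[i] <- m_sub[[i]][2L]
      position[i] <- as.integer(m_sub[[i]][3L])
      alta[i] <- m_sub[[i]][4L]
      if (refa[i] == alta[i])
        stop("malformed variant token (ref equals alt): ", raw[i])
    } else if (length(m_posa[[i]]) == 3L) {
      if (is.null(ref))
        stop("token ", raw[i], " needs a reference to resolve its ref allele")
      kind[i] <- "sub"
      position[i] <- as.integer(m_posa[[i]][2L])
      alta[i] <- m_posa[[i]][3L]
      if (position[i] < 1L || position[i] > ref$length)
        stop("variant position out of range [1, ", ref$length, "]: ", raw[i])
      refa[i] <- ref$chars[position[i]]
      if (refa[i] == alta[i])
        stop("malformed variant token (ref equals alt): ", raw[i])
    } else if (length(m_ins[[i]]) == 4L) {
      kind[i] <- "ins"
      position[i] <- as.integer(m_ins[[i]][2L])
      ins_index[i] <- as.integer(m_ins[[i]][3L])
      alta[i] <- m_ins[[i]][4L]
      refa[i] <- ""
      if (ins_index[i] < 1L)
        stop("malformed variant token (insertion index must be >= 1): ", raw[i])
    } else if (length(m_del[[i]]) == 2L) {
      kind[i] <- "del"
      position[i] <- as.integer(m_del[[i]][2L])
      alta[i] <- ""
      refa[i] <- if (!is.null(ref) && position[i] >= 1L &&
                     position[i] <= ref$length) ref$chars[position[i]] else ""
    } else {
      stop("malformed variant token: ", raw[i])
    }
    if (position[i] < 1L || position[i] > maxlen)
      stop("variant position out of range [1, ", maxlen, "]: ", raw[i])
    if (kind[i] == "sub" && !is.null(ref) &&
        ref$chars[position[i]] != "N" && refa[i] != ref$chars[position[i]])
      stop(sprintf("token %s: reference allele is %s at np %d",
                   raw[i], ref$chars[position[i]], position[i]))
  }
  .make_variants(position, kind, refa, alta, ins_index, back)
}

#' @rdname parse_variants
#' @param token single nomenclature token.
#' @export
parse_variant <- function(token, ref = mt_reference()) {
  if (length(token) != 1L) stop("parse_variant takes a single token")
  parse_variants(token, ref = ref)
}

#' Format variants as canonical nomenclature tokens
#'
#' Inverse of [parse_variants()]: `parse_variants(format_variant(v))` returns
#' `v`.
#'
#' @param v an `mt_variants` table.
#' @return Character vector of canonical tokens.
#' @export
format_variant <- function(v) {
  v <- as_mt_variants(v, ref = NULL)
  v$token
}

#' Coerce tokens or data frames to an `mt_variants` table
#'
#' @param x character tokens, an `mt_variants` table, or a data frame with the
#'   variant columns.
#' @param ref reference used when parsing tokens.
#' @return An `mt_variants` table.
#' @export
as_mt_variants <- function(x, ref = mt_reference()) {
  if (inherits(x, "mt_variants")) return(x)
  if (is.character(x)) return(parse_variants(x, ref = ref))
  if (is.data.frame(x) && all(.mt_variant_cols %in% names(x))) {
    class(x) <- c("mt_variants", "data.frame")
    return(x)
  }
  stop("cannot interpret object as variants")
}

#' @export
print.mt_variants <- function(x, ...) {
  cat(sprintf("<mt_variants> %d variant(s): %s\n", nrow(x),
              paste(utils::head(x$token, 12L), collapse = " ")))
  invisible(x)
}

.dedupe_variants <- function(v) {
  key <- paste(v$position, v$kind, ifelse(is.na(v$ins_index), 0L, v$ins_index))
  v[!duplicated(key), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Variant calling

.align_sample <- function(sample, ref, band) {
  tryCatch(
    .banded_align_cpp(ref$sequence, sample, as.integer(band)),
    error = function(e) {
      if (grepl("band", conditionMessage(e)))
        stop("alignment band (", band, ") exceeded; retry call_variants() ",
             "with a larger `band`", call. = FALSE)
      stop(e)
    })
}

# shift an indel run to its 3'-most equivalent placement within the reference
# context (mtDNA convention). `seq` is the repeated unit context.
.shift3 <- function(start_after, bases, ref_chars, L) {
  k <- length(bases)
  repeat {
    nxt <- start_after + 1L
    if (nxt > L) break
    if (ref_chars[nxt] != bases[1L]) break
    bases <- c(bases[-1L], bases[1L])
    start_after <- nxt
  }
  list(after = start_after, bases = bases)
}

#' Call rCRS-relative variants from a whole-mitogenome sequence
#'
#' Aligns the sample to the reference (vectorised direct comparison when the
#' lengths match and divergence is low; banded global alignment otherwise) and
#' reports every difference in canonical nomenclature. `N` bases yield no
#' calls; masked positions yield no calls but are recorded as excluded.
#' Insertions and deletions are placed at their 3'-most equivalent position.
#'
#' @param sample nucleotide string (A,C,G,T,N).
#' @param ref `mt_reference`, default the packaged reference.
#' @param mask integer positions excluded from calling; default
#'   [default_mask()].
#' @param sample_id identifier stored in the profile.
#' @param band half-width of the alignment band (default 200).
#' @param length_tol maximum tolerated length difference in bases.
#' @param rotate optional circular rotation (bases) applied to the sample
#'   before alignment; 0 by default.
#' @return An `mt_profile`: list with `sample_id`, `variants`
#'   (`mt_variants`), `excluded_sites`.
#' @export
call_variants <- function(sample, ref = mt_reference(), mask = default_mask(),
                          sample_id = "sample", band = 200L,
                          length_tol = 100L, rotate = 0L) {
  sample <- toupper(sample)
  n_smp <- nchar(sample)
  if (abs(n_smp - ref$length) > length_tol)
    stop(sprintf("sample length %d outside tolerance band (reference %d +/- %d)",
                 n_smp, ref$length, length_tol))
  if (grepl("[^ACGTN]", sample))
    stop("sample alphabet restricted to A,C,G,T,N")
  if (rotate != 0L) {
    r <- ((rotate - 1L) %% n_smp) + 1L
    sample <- paste0(substr(sample, r + 1L, n_smp), substr(sample, 1L, r))
  }
  mask <- as.integer(mask)

  sub_pos <- integer(0); sub_alt <- character(0)
  dels <- integer(0)                      # deleted reference positions
  ins_after <- integer(0); ins_idx <- integer(0); ins_base <- character(0)

  fast <- FALSE
  if (n_smp == ref$length) {
    sc <- strsplit(sample, "", fixed = TRUE)[[1L]]
    diffpos <- which(sc != ref$chars)
    if (length(diffpos) <= max(50L, ref$length %/% 50L)) {
      fast <- TRUE
      keep <- sc[diffpos] != "N" & ref$chars[diffpos] != "N"
      sub_pos <- diffpos[keep]; sub_alt <- sc[diffpos][keep]
    }
  }
  if (!fast) {
    al <- .align_sample(sample, ref, band)
    ra <- strsplit(al$ref, "", fixed = TRUE)[[1L]]
    qa <- strsplit(al$qry, "", fixed = TRUE)[[1L]]
    refpos <- cumsum(ra != "-")           # reference coordinate per column
    is_sub <- ra != "-" & qa != "-" & ra != qa & qa != "N" & ra != "N"
    sub_pos <- refpos[is_sub]; sub_alt <- qa[is_sub]
    # deletion runs (gap in query)
    gapq <- which(qa == "-")
    if (length(gapq) > 0L) {
      runs <- split(gapq, cumsum(c(1L, diff(gapq) != 1L)))
      for (r in runs) {
        st <- refpos[r[1L]]; en <- refpos[r[length(r)]]
        bases <- ref$chars[st:en]
        sh <- .shift3(en, bases, ref$chars, ref$length)
        # shifted run now occupies (sh$after - length(bases) + 1) .. sh$after
        dels <- c(dels, seq(sh$after - length(bases) + 1L, sh$after))
      }
    }
    # insertion runs (gap in reference)
    gapr <- which(ra == "-")
    if (length(gapr) > 0L) {
      runs <- split(gapr, cumsum(c(1L, diff(gapr) != 1L)))
      for (r in runs) {
        after <- if (r[1L] == 1L) 0L else refpos[r[1L] - 1L]
        bases <- qa[r]
        if (all(bases == "N")) next
        sh <- .shift3(after, bases, ref$chars, ref$length)
        ins_after <- c(ins_after, rep(sh$after, length(sh$bases)))
        ins_idx <- c(ins_idx, seq_along(sh$bases))
        ins_base <- c(ins_base, sh$bases)
      }
    }
  }

  keep_sub <- !(sub_pos %in% mask)
  keep_del <- !(dels %in% mask)
  keep_ins <- !(ins_after %in% mask)
  v <- .make_variants(
    position = c(sub_pos[keep_sub], dels[keep_del], ins_after[keep_ins]),
    kind = c(rep("sub", sum(keep_sub)), rep("del", sum(keep_del)),
             rep("ins", sum(keep_ins))),
    refa = c(ref$chars[sub_pos[keep_sub]], ref$chars[dels[keep_del]],
             rep("", sum(keep_ins))),
    alta = c(sub_alt[keep_sub], rep("", sum(keep_del)), ins_base[keep_ins]),
    ins_index = c(rep(NA_integer_, sum(keep_sub) + sum(keep_del)),
                  ins_idx[keep_ins]),
    back = rep(FALSE, sum(keep_sub) + sum(keep_del) + sum(keep_ins))
  )
  v <- v[order(v$position, v$kind, v$ins_index, method = "radix"), ,
         drop = FALSE]
  rownames(v) <- NULL
  class(v) <- c("mt_variants", "data.frame")
  mt_profile(sample_id, v, excluded_sites = sort(unique(mask)))
}

#' Construct a variant profile
#'
#' @param sample_id identifier.
#' @param variants `mt_variants` table or character tokens.
#' @param excluded_sites integer positions masked during calling.
#' @param ref reference used when parsing tokens.
#' @return An `mt_profile`.
#' @export
mt_profile <- function(sample_id, variants, excluded_sites = integer(0),
                       ref = mt_reference()) {
  v <- .dedupe_variants(as_mt_variants(variants, ref = ref))
  structure(list(sample_id = sample_id, variants = v,
                 excluded_sites = as.integer(excluded_sites)),
            class = "mt_profile")
}

#' @export
print.mt_profile <- function(x, ...) {
  cat(sprintf("<mt_profile> %s: %d variant(s), %d excluded site(s)\n",
              x$sample_id, nrow(x$variants), length(x$excluded_sites)))
  invisible(x)
}

#' Call variants for every record of a FASTA file
#'
#' @param x path to a multi-record FASTA file, or a
#'   [Biostrings::DNAStringSet].
#' @inheritParams call_variants
#' @return Named list of `mt_profile` objects (names = record ids).
#' @export
call_variants_fasta <- function(x, ref = mt_reference(),
                                mask = default_mask(), ...) {
  ss <- if (inherits(x, "DNAStringSet")) x else Biostrings::readDNAStringSet(x)
  if (length(ss) == 0L) stop("FASTA contains no records")
  ids <- sub("\\s.*$", "", names(ss))
  out <- lapply(seq_along(ss), function(i)
    call_variants(as.character(ss[[i]]), ref = ref, mask = mask,
                  sample_id = ids[i], ...))
  stats::setNames(out, ids)
}

#' Write per-sample variant profiles as TSV
#'
#' Two columns: sample_id and the space-separated canonical token list.
#'
#' @param profiles list of `mt_profile`.
#' @param path output file.
#' @export
write_profiles_tsv <- function(profiles, path) {
  df <- data.frame(
    sample_id = vapply(profiles, function(p) p$sample_id, character(1)),
    variants = vapply(profiles, function(p)
      paste(p$variants$token, collapse = " "), character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write variant profiles as a minimal VCF
#'
#' Substitution/deletion/insertion records on contig `chrM` (length 16,569),
#' one sample column per profile, GT 1 when the sample carries the variant.
#'
#' @param profiles list of `mt_profile`.
#' @param path output file.
#' @param ref `mt_reference`.
#' @export
write_profiles_vcf <- function(profiles, path, ref = mt_reference()) {
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  all_v <- unique(do.call(rbind, lapply(profiles, function(p) p$variants)))
  all_v <- all_v[order(all_v$position, all_v$kind, all_v$ins_index,
                       method = "radix"), , drop = FALSE]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=chrM,length=%d>", ref$length),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  if (is.null(all_v) || nrow(all_v) == 0L) return(invisible(path))
  carrier <- vapply(profiles, function(p) all_v$token %in% p$variants$token,
                    logical(nrow(all_v)))
  carrier <- matrix(carrier, nrow = nrow(all_v))
  for (i in seq_len(nrow(all_v))) {
    p <- all_v$position[i]
    rec <- switch(all_v$kind[i],
      sub = c(p, all_v$ref[i], all_v$alt[i]),
      del = c(p - 1L, paste0(ref$chars[p - 1L], ref$chars[p]),
              ref$chars[p - 1L]),
      ins = c(p, ref$chars[p], paste0(ref$chars[p], all_v$alt[i])))
    gt <- ifelse(carrier[i, ], "1", "0")
    writeLines(paste(c("chrM", rec[1L], all_v$token[i], rec[2L], rec[3L],
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}
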