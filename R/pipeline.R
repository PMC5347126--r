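# End-to-end orchestration: FASTA -> variant profiles -> classification ->
# per-clade maximum-parsimony trees -> TMRCA report.

#' Build a pipeline run configuration
#'
#' @param input path to a multi-record FASTA of whole mitogenomes (`NULL` when
#'   `simulate = TRUE`).
#' @param out_dir output directory (created if missing).
#' @param tree path to a haplogroup definition file, or `NULL` for the
#'   packaged `australia_2017` tree.
#' @param clocks list of `mt_clock`s; default Fu and Soares.
#' @param mask excluded positions; default [default_mask()].
#' @param weights `site_weights`; default [default_site_weights()] built from
#'   `mask`.
#' @param simulate when `TRUE`, generate the default study cohort (with
#'   `seed`) instead of reading `input`.
#' @param seed integer seed for the simulate stage.
#' @param band,length_tol alignment parameters for [call_variants()].
#' @param verbose emit progress messages.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, out_dir = "mitorho_out", tree = NULL,
                       clocks = list(clock_fu(), clock_soares()),
                       mask = default_mask(), weights = NULL,
                       simulate = FALSE, seed = 1L, band = 200L,
                       length_tol = 100L, verbose = TRUE) {
  if (is.null(weights)) weights <- default_site_weights(mask = mask)
  if (!simulate) {
    if (is.null(input)) stop("config needs an input FASTA (or simulate = TRUE)")
    if (!file.exists(input)) stop("input file does not exist: ", input)
  }
  if (!is.null(tree) && !file.exists(tree))
    stop("tree definition file does not exist: ", tree)
  structure(list(input = input, out_dir = out_dir, tree = tree,
                 clocks = clocks, mask = as.integer(mask), weights = weights,
                 simulate = isTRUE(simulate), seed = as.integer(seed),
                 band = as.integer(band), length_tol = as.integer(length_tol),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys: `input`, `out_dir`, `tree`, `simulate`, `seed`, `band`,
#' `length_tol`, `mask` (vector of positions), `weights` (map position ->
#' weight) and `clocks`, a list of maps with keys `name`, `mode`, `value`,
#' `low`, `high`, `genome_length`.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  clocks <- if (is.null(y$clocks)) list(clock_fu(), clock_soares())
    else lapply(y$clocks, function(ck)
      mt_clock(ck$name, ck$mode, ck$value,
               rate_low = ck$low, rate_high = ck$high,
               genome_length = if (is.null(ck$genome_length)) 16569L
                               else ck$genome_length))
  mask <- if (is.null(y$mask)) default_mask() else as.integer(y$mask)
  weights <- if (is.null(y$weights)) NULL
    else site_weights(c(stats::setNames(rep(0, length(mask)), mask),
                        unlist(y$weights)))
  args <- list(input = y$input, tree = y$tree, clocks = clocks, mask = mask,
               weights = weights)
  for (k in c("out_dir", "simulate", "seed", "band", "length_tol", "verbose"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(run_config, args)
}

.plog <- function(cfg, ...) {
  line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  if (cfg$verbose) message(line)
  logfile <- file.path(cfg$out_dir, "run.log")
  if (dir.exists(cfg$out_dir)) cat(line, "\n", file = logfile, append = TRUE)
  invisible(NULL)
}

#' Run the full pipeline
#'
#' Stages: (1) read or simulate the cohort FASTA; (2) call rCRS-relative
#' variants per sample; (3) classify each profile against the haplogroup
#' tree; (4) per assigned clade, build the maximum-parsimony sample tree and
#' estimate the TMRCA under every configured clock. Writes
#' `classification.tsv`, `variants.tsv`, one `tree_<clade>.nwk` per clade,
#' `tmrca.tsv` (point estimate and interval per clock, in KY) and `run.log`
#' into the output directory. Masked sites and classification ties are
#' logged.
#'
#' @param cfg a `run_config` (or YAML path, forwarded to
#'   [read_run_config()]).
#' @return Invisibly, a list with `profiles`, `classification`, `trees`,
#'   `tmrca` (data frame), and the output paths.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stage <- "input"
  result <- tryCatch({
    tree <- if (is.null(cfg$tree)) australia_tree()
            else load_haplotree(cfg$tree)
    if (cfg$simulate) {
      cohort <- default_study_cohort(seed = cfg$seed, tree = tree)
      sequences <- cohort$sequences
    } else {
      sequences <- Biostrings::readDNAStringSet(cfg$input)
      if (length(sequences) == 0L) stop("input FASTA contains no records")
      cohort <- NULL
    }
    if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
    .plog(cfg, "input: ", length(sequences), " sequence(s)")
    .plog(cfg, "masked sites: ", paste(cfg$mask, collapse = ","))
    if (!is.null(cohort)) {
      Biostrings::writeXStringSet(sequences,
                                  file.path(cfg$out_dir, "cohort.fasta"),
                                  width = 70L)
      utils::write.table(cohort$sample_sheet,
                         file.path(cfg$out_dir, "sample_sheet.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    stage <- "call"
    profiles <- call_variants_fasta(sequences, mask = cfg$mask,
                                    band = cfg$band,
                                    length_tol = cfg$length_tol)
    write_profiles_tsv(profiles, file.path(cfg$out_dir, "variants.tsv"))
    .plog(cfg, "called variants for ", length(profiles), " sample(s)")

    stage <- "classify"
    classification <- classify_cohort(profiles, tree, cfg$weights)
    for (i in which(classification$tie))
      .plog(cfg, "classification tie: ", classification$sample_id[i],
            " at ", classification$haplogroup[i])
    write_classification_tsv(classification,
                             file.path(cfg$out_dir, "classification.tsv"))
    .plog(cfg, "classified ", nrow(classification), " sample(s)")

    stage <- "tmrca"
    clades <- sort(unique(classification$haplogroup))
    clades <- setdiff(clades, tree$root)
    estimates <- list(); trees <- list()
    for (cl in clades) {
      in_clade <- vapply(classification$haplogroup, function(h)
        cl %in% haplo_path(tree, h), logical(1))
      members <- profiles[in_clade]
      root_profile <- mt_profile(cl, cumulative_expected(tree, cl))
      st <- build_mp_tree(members, root_profile, w = cfg$weights)
      trees[[cl]] <- st
      writeLines(sample_tree_newick(st),
                 file.path(cfg$out_dir,
                           paste0("tree_", gsub("[^A-Za-z0-9]", "_", cl),
                                  ".nwk")))
      rho <- compute_rho(st); sigma <- compute_sigma(st)
      for (ck in cfg$clocks)
        estimates[[length(estimates) + 1L]] <-
          rho_to_time(rho, sigma, ck, n = st$n_tips, haplogroup = cl)
    }
    tmrca <- tmrca_table(estimates)
    utils::write.table(tmrca, file.path(cfg$out_dir, "tmrca.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .plog(cfg, "TMRCA estimated for ", length(clades), " clade(s) under ",
          length(cfg$clocks), " clock(s)")

    list(profiles = profiles, classification = classification, trees = trees,
         tmrca = tmrca,
         paths = list(
           classification = file.path(cfg$out_dir, "classification.tsv"),
           variants = file.path(cfg$out_dir, "variants.tsv"),
           tmrca = file.path(cfg$out_dir, "tmrca.tsv")))
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
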