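# Shared readers/writers and the end-to-end pipeline driver. TSV is the
# canonical tabular format (CSV accepted on read); BED interval input is
# converted from 0-based half-open to the package-internal 1-based
# inclusive convention on ingest.

#' Read a numeric matrix from TSV/CSV
#'
#' First column holds row identifiers, header row holds column identifiers.
#' Empty strings, `NA` and `NaN` parse as missing. Duplicate identifiers
#' and non-numeric cells are errors (with coordinates).
#'
#' @param path File path (`.tsv`/`.txt` tab-separated or `.csv`).
#' @param orientation `"features"` (default: rows are features, kept as-is)
#'   or `"samples"` (rows are samples; the matrix is transposed so features
#'   end up in rows).
#' @return Numeric matrix with dimnames.
#' @export
read_matrix <- function(path, orientation = c("features", "samples")) {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", tolower(path))) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("", "NA", "NaN"),
                           colClasses = "character", comment.char = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L) stop("empty matrix in ", path)
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate row identifier(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  cols <- colnames(raw)[-1]
  if (anyDuplicated(cols)) {
    stop("duplicate column identifier(s) in ", path, ": ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "))
  }
  body <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow(body), ncol(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                 ids[bad[1, 1]], cols[bad[1, 2]], path))
  }
  dimnames(num) <- list(ids, cols)
  if (orientation == "samples") num <- t(num)
  num
}

#' Write a numeric matrix as TSV
#'
#' @param x Matrix with dimnames.
#' @param path Output path.
#' @param id_name Header of the identifier column (default `"id"`).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, id_name = "id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a data frame as TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED region set
#'
#' BED3+ input (0-based half-open) is imported with rtracklayer, which
#' yields the 1-based inclusive coordinates used internally. Output is
#' sorted; the BED name column is preserved as region names when present.
#'
#' @param path Path to a BED file.
#' @return Sorted [GenomicRanges::GRanges].
#' @export
read_regions <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  if (!is.null(gr$name) && !anyNA(gr$name)) names(gr) <- gr$name
  gr
}

#' Write a region set as BED
#'
#' Converts from the internal 1-based inclusive convention back to BED's
#' 0-based half-open on output.
#'
#' @param gr [GenomicRanges::GRanges].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(gr, path) {
  if (!is.null(names(gr))) gr$name <- names(gr)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a chromosome-sizes file
#'
#' Two whitespace-separated columns: chromosome name, length in bp.
#'
#' @param path File path.
#' @return Named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("chromosome-sizes file needs two columns: ", path)
  stats::setNames(as.numeric(tab[[2]]), tab[[1]])
}

#' Run the synthetic end-to-end pipeline
#'
#' Generates seeded synthetic inputs for the configured stages and runs
#' each analysis on them, writing stage outputs as TSV plus a
#' `manifest.json` recording every parameter, seed and output file. Any
#' stage failure aborts with the stage name. Reruns with an identical
#' config reproduce deterministic outputs byte-identically.
#'
#' @param config A list (or path to a YAML file) with elements `seed`
#'   (integer) and optionally `stages` (subset of `c("content",
#'   "harmonize", "ase", "asm", "dependency", "enrichment")`; default all)
#'   plus per-stage parameter lists overriding generator defaults.
#' @param out_dir Output directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stages <- if (is.null(config$stages)) {
    c("content", "harmonize", "ase", "asm", "dependency", "enrichment")
  } else config$stages
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, stages = stages, outputs = list())

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  arg <- function(stage, defaults) {
    utils::modifyList(defaults, if (is.null(config[[stage]])) list() else config[[stage]])
  }

  if ("content" %in% stages) {
    run_stage("content", function() {
      prm <- arg("content", list(n_reads = 50000L, read_length = 100L,
                                 telomere_fraction = 0.001))
      sim <- simulate_reads(prm$n_reads, prm$read_length,
                            prm$telomere_fraction, seed = seed)
      est <- estimate_content(sim$reads, sample = "sim_sample",
                              source = "simulated")
      path <- file.path(out_dir, "content.tsv")
      write_tsv(est, path)
      manifest$outputs$content <<- list(file = "content.tsv", params = prm)
    })
  }
  if ("harmonize" %in% stages) {
    run_stage("harmonize", function() {
      prm <- arg("harmonize", list(n_per_batch = 200L, delta = 1.5))
      sim <- simulate_batched_content(prm$n_per_batch, prm$delta, seed = seed)
      z <- log_z(sim$content$raw_length_kb)
      labels <- detect_batches(sim$content[, c("freq4", "freq5", "freq6")],
                               seed = seed)
      corrected <- recenter(z, labels)
      out <- data.frame(sample = sim$content$sample, z = as.numeric(z),
                        batch = labels, corrected = corrected)
      path <- file.path(out_dir, "harmonized.tsv")
      write_tsv(out, path)
      manifest$outputs$harmonize <<- list(file = "harmonized.tsv", params = prm)
    })
  }
  if ("ase" %in% stages) {
    run_stage("ase", function() {
      prm <- arg("ase", list(n = 500L, or_threshold = 5))
      sim <- simulate_allele_counts(n = prm$n, seed = seed)
      calls <- call_ase(sim$counts, or_threshold = prm$or_threshold)
      write_tsv(calls, file.path(out_dir, "ase_calls.tsv"))
      manifest$outputs$ase <<- list(file = "ase_calls.tsv", params = prm)
    })
  }
  if ("asm" %in% stages) {
    run_stage("asm", function() {
      prm <- arg("asm", list(n_pairs = 50L, n_samples = 40L, purity = 0.95))
      sim <- simulate_cpg_pairs(n_pairs = prm$n_pairs,
                                n_samples = prm$n_samples,
                                purity = prm$purity, seed = seed)
      scored <- score_pairs(sim$pairs)
      write_tsv(scored, file.path(out_dir, "asm_pairs.tsv"))
      manifest$outputs$asm <<- list(file = "asm_pairs.tsv", params = prm)
    })
  }
  if ("dependency" %in% stages) {
    run_stage("dependency", function() {
      prm <- arg("dependency", list(n_genes = 50L, n_samples = 200L))
      sim <- simulate_dependency_screen(n_genes = prm$n_genes,
                                        n_samples = prm$n_samples, seed = seed)
      expanded <- codependency_expand(sim$dep, sim$truth$module_genes[1:3])
      assoc <- signed_q(mutation_associations(sim$dep, sim$mut))
      writeLines(expanded, file.path(out_dir, "codependency_members.txt"))
      write_tsv(assoc, file.path(out_dir, "mutation_associations.tsv"))
      manifest$outputs$dependency <<- list(
        files = c("codependency_members.txt", "mutation_associations.tsv"),
        params = prm)
    })
  }
  if ("enrichment" %in% stages) {
    run_stage("enrichment", function() {
      prm <- arg("enrichment", list(n_cgis = 2000L, n_planted = 100L,
                                    n_decoys = 5L, top_n = 400L))
      sim <- simulate_methylation_cohort(n_cgis = prm$n_cgis,
                                         n_planted = prm$n_planted,
                                         n_decoys = prm$n_decoys, seed = seed)
      ranked <- rank_differential_cgis(sim$meth, sim$groups)
      interest <- sim$universe[select_interest(ranked, n = prm$top_n)]
      enr <- region_set_enrichment(interest, sim$universe, sim$sets)
      write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
      manifest$outputs$enrichment <<- list(file = "enrichment.tsv", params = prm)
    })
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
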