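# End-to-end orchestration: a single validated config drives the stages
# (simulate -> intergenic -> normfactors -> density -> metagene ->
# tssprofile -> cluster -> travel -> declassify -> report), each writing
# its artifacts atomically under one output directory together with a
# run manifest.  The functions are the entry point; wrapping them in an
# Rscript is a one-liner.

#' Build a pipeline run configuration
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed for every stochastic stage.
#' @param simulate `NULL`, or a list of [simulate_genome()] /
#'   [sim_truth()] / [simulate_de_table()] arguments (any subset;
#'   defaults fill the rest) to run on synthetic data.
#' @param inputs When not simulating: list with paths `annotation`,
#'   `chrom_sizes`, `de_table` and `tags` (a list per mark of named
#'   per-sample BED paths).
#' @param normalization Named character vector mapping each mark to
#'   `"intergenic"` or `"total"`.
#' @param intergenic List: `min_len_bp`, `gene_buffer_bp`.
#' @param expression List: `min_density` (reads/kb threshold).
#' @param density List: `extension_bp`, `scale_const`, `min_reads`.
#' @param profile A [profile_config()].
#' @param pausing A [pausing_config()].
#' @param de List: `padj_max`, `min_abs_log2fc`, `fold_bins`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(outdir, seed = 1L, simulate = list(), inputs = NULL,
                       normalization = c(H2Bub1 = "intergenic",
                                         PolII = "total",
                                         PolII_Ser2P = "total"),
                       intergenic = list(min_len_bp = 100000L,
                                         gene_buffer_bp = 10000L),
                       expression = list(min_density = 10),
                       density = list(extension_bp = 200L,
                                      scale_const = 1e-8, min_reads = 1L),
                       profile = profile_config(),
                       pausing = pausing_config(),
                       de = list(padj_max = 0.05, min_abs_log2fc = 1,
                                 fold_bins = c(2, 4, 8, 32, 64, 128, 256))) {
  structure(list(outdir = outdir, seed = as.integer(seed),
                 simulate = simulate, inputs = inputs,
                 normalization = normalization, intergenic = intergenic,
                 expression = expression, density = density,
                 profile = profile, pausing = pausing, de = de),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Checks modes and, for file-based runs, that every referenced path
#' exists; errors name the offending key.
#'
#' @param config A [run_config()].
#' @return The config, invisibly, when valid.
#' @export
validate_run_config <- function(config) {
  if (is.null(config$outdir)) abort("config key 'outdir' is missing")
  bad_mode <- !config$normalization %in% c("intergenic", "total")
  if (any(bad_mode)) {
    abort(paste0("config key 'normalization': mode for ",
                 names(config$normalization)[bad_mode][1],
                 " must be 'intergenic' or 'total'"))
  }
  if (is.null(config$simulate)) {
    req <- c("annotation", "chrom_sizes")
    for (key in req) {
      p <- config$inputs[[key]]
      if (is.null(p) || !file.exists(p)) {
        abort(paste0("config key 'inputs$", key,
                     "': path missing or does not exist: ",
                     p %||% "<NULL>"))
      }
    }
    for (mark in names(config$inputs$tags)) {
      for (s in names(config$inputs$tags[[mark]])) {
        p <- config$inputs$tags[[mark]][[s]]
        if (!file.exists(p)) {
          abort(paste0("config key 'inputs$tags$", mark, "$", s,
                       "': path does not exist: ", p))
        }
      }
    }
  }
  invisible(config)
}

write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

write_tsv_atomic <- function(x, path) {
  write_atomic(function(p) readr::write_tsv(x, p), path)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order against a validated config.
#' With a `simulate` config the synthetic genome, truth and tag
#' libraries are generated first and feed every later stage; otherwise
#' inputs are read from the configured paths.  All outputs are TSV/BED
#' files under `config$outdir`, written atomically, plus a
#' `manifest.json` recording the package version, seed and config hash.
#'
#' @param config A [run_config()].
#' @param stages Character vector of stages to run (default: all).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "intergenic", "normfactors",
                                    "density", "metagene", "tssprofile",
                                    "cluster", "travel", "declassify",
                                    "report")) {
  validate_run_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  t0 <- Sys.time()
  stage_msg <- function(name) {
    message(sprintf("[%s] stage %-11s (%.1fs elapsed)", "chipmetrics", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  if ("simulate" %in% stages && !is.null(config$simulate)) {
    stage_msg("simulate")
    sim <- config$simulate
    genome <- simulate_genome(
      n_genes = sim$n_genes %||% 300L,
      gene_len_range = sim$gene_len_range %||% c(2000L, 8000L),
      gap_range = sim$gap_range %||% c(20000L, 40000L),
      seed = config$seed)
    truth <- sim_truth(
      genome$genes, seed = config$seed,
      background_rate = sim$background_rate %||% 0.001,
      body_rate = sim$body_rate %||% 0.05,
      h2bub_fold = sim$h2bub_fold %||% 1,
      pausing_ratio = sim$pausing_ratio %||% 4,
      depth = sim$depth %||% c(WT = 1, KO = 1))
    marks <- sim$marks %||% c("H2Bub1", "PolII")
    tags <- purrr::map(setNames(marks, marks), function(mark) {
      purrr::map(setNames(names(truth$depth), names(truth$depth)),
                 function(s) simulate_tags(truth, s, mark,
                                           genome$chrom_sizes))
    })
    # every simulated gene counts as expressed: base-median chosen so
    # that base_median / tx_len_kb comfortably clears both filters
    de_like <- tibble(gene_id = genome$genes$gene_id,
                      base_median = 200 * genome$genes$median_tx_len_kb,
                      log2fc = 0, padj = 1)
    res$genes <- genome$genes
    res$chrom_sizes <- genome$chrom_sizes
    res$truth <- truth
    res$tags <- tags
    res$expression <- de_like
    write_atomic(function(p) write_gene_bed(genome$genes, p),
                 file.path(config$outdir, "annotation.bed"))
    write_atomic(function(p) write_chrom_sizes(genome$chrom_sizes, p),
                 file.path(config$outdir, "chrom.sizes"))
    for (mark in names(tags)) {
      for (s in names(tags[[mark]])) {
        write_atomic(
          function(p) write_tag_bed(tags[[mark]][[s]], p,
                                    read_len = truth$read_len_bp,
                                    header = paste0("seed=", config$seed,
                                                    " sample=", s,
                                                    " mark=", mark)),
          file.path(config$outdir, paste0("tags_", mark, "_", s, ".bed")))
      }
    }
  } else if (is.null(config$simulate)) {
    res$genes <- read_annotation(config$inputs$annotation)
    res$chrom_sizes <- read_chrom_sizes(config$inputs$chrom_sizes)
    res$tags <- purrr::map(config$inputs$tags,
                           function(x) purrr::map(x, read_tag_bed))
    res$expression <- if (!is.null(config$inputs$de_table)) {
      read_de_table(config$inputs$de_table)
    } else NULL
  }

  if ("intergenic" %in% stages) {
    stage_msg("intergenic")
    res$intergenic <- select_intergenic(
      res$genes, res$chrom_sizes,
      min_len_bp = config$intergenic$min_len_bp,
      gene_buffer_bp = config$intergenic$gene_buffer_bp)
    write_atomic(function(p) write_region_bed(res$intergenic, p),
                 file.path(config$outdir, "intergenic.bed"))
  }

  if ("normfactors" %in% stages) {
    stage_msg("normfactors")
    res$size_factors <- purrr::imap(res$tags, function(samples, mark) {
      mode <- config$normalization[[mark]] %||% "total"
      if (mode == "intergenic") {
        counts <- region_counts(res$intergenic, samples)
        size_factors_intergenic(counts)
      } else {
        size_factors_total(vapply(samples, nrow, integer(1)))
      }
    })
    sf_tbl <- purrr::imap(res$size_factors, function(sf, mark) {
      tibble(mark = mark, sample = names(sf), size_factor = unname(sf))
    }) |> bind_rows()
    write_tsv_atomic(sf_tbl, file.path(config$outdir, "size_factors.tsv"))
  }

  expressed_genes <- function() {
    if (is.null(res$expression)) return(res$genes)
    keep <- filter_expressed(res$expression, res$genes,
                             min_density = config$expression$min_density)
    res$genes[res$genes$gene_id %in% keep$gene_id, , drop = FALSE]
  }

  if ("density" %in% stages) {
    stage_msg("density")
    res$density <- purrr::imap(res$tags, function(samples, mark) {
      density_table(expressed_genes(), samples, res$size_factors[[mark]],
                    extension_bp = config$density$extension_bp,
                    scale_const = config$density$scale_const,
                    min_reads = config$density$min_reads,
                    chrom_sizes = res$chrom_sizes)
    })
    for (mark in names(res$density)) {
      write_tsv_atomic(res$density[[mark]],
                       file.path(config$outdir,
                                 paste0("density_", mark, ".tsv")))
    }
    res$fold <- purrr::imap(res$density, function(d, mark) {
      wide <- tidyr::pivot_wider(d[, c("gene_id", "sample", "density")],
                                 names_from = "sample",
                                 values_from = "density")
      samples <- intersect(names(res$tags[[mark]]), names(wide))
      if (length(samples) != 2) return(NULL)
      wt_dens <- wide[[samples[1]]]
      ko_dens <- wide[[samples[2]]]
      tibble(mark = mark, wt = samples[1], ko = samples[2],
             fold = fold_change_summary(wt_dens, ko_dens),
             wilcoxon_p = rank_sum_test(wt_dens, ko_dens)$p_value)
    }) |> bind_rows()
    write_tsv_atomic(res$fold, file.path(config$outdir, "fold_summary.tsv"))
  }

  if ("metagene" %in% stages) {
    stage_msg("metagene")
    res$metagene <- purrr::imap(res$tags, function(samples, mark) {
      purrr::imap(samples, function(tags, s) {
        suppressMessages(metagene_profile(
          expressed_genes(), tags,
          size_factor = res$size_factors[[mark]][[s]],
          cfg = config$profile, chrom_sizes = res$chrom_sizes,
          sample = paste0(mark, "_", s)))
      }) |> bind_rows()
    }) |> bind_rows()
    write_tsv_atomic(res$metagene, file.path(config$outdir, "metagene.tsv"))
  }

  if ("tssprofile" %in% stages) {
    stage_msg("tssprofile")
    res$tss_profiles <- purrr::imap(res$tags, function(samples, mark) {
      purrr::imap(samples, function(tags, s) {
        tss_profile(expressed_genes(), tags,
                    size_factor = res$size_factors[[mark]][[s]],
                    cfg = config$profile, chrom_sizes = res$chrom_sizes,
                    sample = paste0(mark, "_", s))
      }) |> bind_rows()
    }) |> bind_rows()
    write_tsv_atomic(res$tss_profiles,
                     file.path(config$outdir, "tss_profiles.tsv"))
  }

  if ("cluster" %in% stages && length(res$tags)) {
    stage_msg("cluster")
    mark <- names(res$tags)[1]
    s <- names(res$tags[[mark]])[1]
    mat <- suppressMessages(profile_matrix(
      expressed_genes(), res$tags[[mark]][[s]],
      size_factor = res$size_factors[[mark]][[s]],
      cfg = config$profile, chrom_sizes = res$chrom_sizes))
    res$clusters <- cluster_profiles(mat, k = 2, seed = config$seed)
    write_tsv_atomic(tidy(res$clusters),
                     file.path(config$outdir, "clusters.tsv"))
  }

  if ("travel" %in% stages && "PolII" %in% names(res$tags)) {
    stage_msg("travel")
    trg <- if (!is.null(res$expression)) {
      tr_gene_set(res$genes, res$expression)
    } else res$genes
    res$tr <- purrr::imap(res$tags$PolII, function(tags, s) {
      suppressMessages(traveling_ratio(
        trg, tags, size_factor = res$size_factors$PolII[[s]],
        cfg = config$pausing, chrom_sizes = res$chrom_sizes))
    })
    if (length(res$tr) == 2) {
      res$tr_comparison <- tr_compare(res$tr[[1]], res$tr[[2]],
                                      labels = names(res$tr))
    }
    tr_tbl <- purrr::imap(res$tr, function(t, s) mutate(t, sample = s)) |>
      bind_rows()
    write_tsv_atomic(tr_tbl, file.path(config$outdir, "traveling_ratio.tsv"))
  }

  if ("declassify" %in% stages) {
    stage_msg("declassify")
    de_tbl <- if (!is.null(config$simulate)) {
      simulate_de_table(
        n_genes = config$simulate$de_n_genes %||% 1000L,
        frac_up = config$simulate$de_frac_up %||% 0.05,
        frac_down = config$simulate$de_frac_down %||% 0.05,
        effect_log2fc = config$simulate$de_effect_log2fc %||% 3,
        seed = config$seed)
    } else res$expression
    if (!is.null(de_tbl) && "log2fc" %in% names(de_tbl)) {
      res$de_classified <- classify_de(de_tbl,
                                       padj_max = config$de$padj_max,
                                       min_abs_log2fc = config$de$min_abs_log2fc)
      res$de_bins <- fold_bin_counts(de_tbl,
                                     fold_bins = config$de$fold_bins,
                                     padj_max = config$de$padj_max)
      write_tsv_atomic(res$de_classified,
                       file.path(config$outdir, "de_classified.tsv"))
      write_tsv_atomic(res$de_bins,
                       file.path(config$outdir, "de_fold_bins.tsv"))
    }
  }

  if ("report" %in% stages) {
    stage_msg("report")
    rows <- list()
    add <- function(stage, metric, value) {
      rows[[length(rows) + 1L]] <<- tibble(stage = stage, metric = metric,
                                           value = as.numeric(value))
    }
    add("genome", "n_genes", nrow(res$genes))
    if (!is.null(res$intergenic)) {
      add("intergenic", "n_regions", nrow(res$intergenic))
    }
    if (!is.null(res$fold) && nrow(res$fold)) {
      for (i in seq_len(nrow(res$fold))) {
        add("density", paste0("fold_", res$fold$mark[i]), res$fold$fold[i])
      }
    }
    if (!is.null(res$tr_comparison)) {
      add("travel", "ks_D", res$tr_comparison$ks$D)
      add("travel", "ks_p", res$tr_comparison$ks$p_value)
    }
    if (!is.null(res$de_classified)) {
      sets <- de_sets(res$de_classified)
      add("de", "n_up", length(sets$up))
      add("de", "n_down", length(sets$down))
    }
    res$report <- bind_rows(rows)
    write_tsv_atomic(res$report, file.path(config$outdir, "report.tsv"))
  }

  manifest <- list(package = "chipmetrics",
                   version = as.character(utils::packageVersion("chipmetrics")),
                   seed = config$seed,
                   config_hash = rlang::hash(unclass(config)),
                   stages = stages,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  write_atomic(function(p) jsonlite::write_json(manifest, p,
                                                auto_unbox = TRUE,
                                                pretty = TRUE),
               file.path(config$outdir, "manifest.json"))
  invisible(res)
}
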