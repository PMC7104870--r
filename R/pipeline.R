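#' Run the full virus-host codon usage analysis
#'
#' Single entry point over the whole toolkit: reads the virus and host CDS
#' FASTA files, runs the three analysis branches — nucleotide content
#' (GC profiles, PR2), gene-level codon usage bias (ENc, SCUO, CAI, RCDI)
#' and codon-level analysis (RSCU, SiD) — plus the dinucleotide null-model
#' z-scores, and writes tidy TSV outputs, the two diagnostic plots and a
#' resolved-config JSON into `output_dir`. The branches are independent of
#' one another except for the stated dependency inside the gene branch: the
#' CAI reference set is the lowest-ENc fraction of host genes.
#'
#' @param virus_path,host_path CDS FASTA paths (plain or gzip).
#' @param output_dir Output directory, created if needed; `NULL` skips all
#'   file output and just returns the result object.
#' @param analyses Which branches to run; any subset of `"composition"`,
#'   `"gene"`, `"codon"`, `"dinucleotide"`.
#' @param policy CDS validation policy (see [read_cds()]).
#' @param enc_method ENc estimator, `"novembre"` (default) or `"wright"`.
#' @param cai_fraction Fraction of lowest-ENc host genes forming the CAI
#'   reference set.
#' @param dinuc_model,n_perm,replacement,seed Dinucleotide null-model
#'   settings (see [dinuc_zscore()]); `seed` also names the run's RNG seed
#'   in the config.
#' @param write_plots Write PNG plots alongside the coordinate TSVs.
#' @param table_id NCBI translation table identifier.
#' @return An object of class `codon_coadaptation`: a list of the computed
#'   tibbles (`gc`, `pr2`, `gene_indices`, `host_enc`, `rscu_virus`,
#'   `rscu_host`, `sid`, `dinuc`), the rejection logs and the resolved
#'   config. Supports [generics::tidy()], [generics::glance()], `print()`
#'   and [ggplot2::autoplot()].
#' @export
run_codon_analysis <- function(virus_path, host_path, output_dir = NULL,
                               analyses = c("composition", "gene", "codon",
                                            "dinucleotide"),
                               policy = "strict",
                               enc_method = "novembre",
                               cai_fraction = 0.05,
                               dinuc_model = "base", n_perm = 500L,
                               replacement = "without", seed = 1L,
                               write_plots = TRUE, table_id = 1L) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  config <- list(
    virus_path = virus_path, host_path = host_path,
    analyses = analyses, policy = policy, enc_method = enc_method,
    cai_fraction = cai_fraction, dinuc_model = dinuc_model,
    n_perm = as.integer(n_perm), replacement = replacement,
    seed = as.integer(seed), table_id = as.integer(table_id)
  )
  pair <- read_virus_host_pair(virus_path, host_path, policy, table_id)
  virus <- pair$virus
  host <- pair$host
  res <- list(config = config,
              virus_rejections = cds_rejections(virus),
              host_rejections = cds_rejections(host),
              n_virus = nrow(virus), n_host = nrow(host))

  if ("composition" %in% analyses) {
    res$gc <- gc_content(virus)
    res$pr2 <- pr2_coordinates(virus, table_id = table_id)
  }
  if ("gene" %in% analyses) {
    venc <- enc(virus, method = enc_method, table_id = table_id)
    res$host_enc <- enc(host, method = enc_method, table_id = table_id)
    ref <- select_reference_set(res$host_enc, cai_fraction)
    wts <- cai_weights(host, reference_ids = ref, table_id = table_id)
    res$reference_ids <- ref
    res$cai_weights <- wts
    res$gene_indices <- venc |>
      dplyr::select("gene_id", "enc") |>
      dplyr::left_join(scuo(virus, table_id = table_id), by = "gene_id") |>
      dplyr::left_join(cai(virus, wts, table_id = table_id), by = "gene_id") |>
      dplyr::left_join(rcdi(virus, host, table_id = table_id),
                       by = "gene_id") |>
      dplyr::left_join(
        dplyr::select(gc_content(virus), "gene_id", "gc3"), by = "gene_id")
  }
  if ("codon" %in% analyses) {
    res$rscu_virus <- rscu(virus, table_id = table_id)
    res$rscu_host <- rscu(host, table_id = table_id)
    res$sid <- sid(virus, host, table_id = table_id)
  }
  if ("dinucleotide" %in% analyses) {
    res$dinuc <- dinuc_zscore(virus, model = dinuc_model, n_perm = n_perm,
                              seed = seed, replacement = replacement,
                              table_id = table_id)
  }
  class(res) <- "codon_coadaptation"
  if (!is.null(output_dir)) {
    write_analysis(res, virus, output_dir, write_plots, table_id)
  }
  res
}

# Write the TSV/plot/config outputs of a finished analysis.
write_analysis <- function(res, virus, output_dir, write_plots, table_id) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(output_dir, f)
  jsonlite::write_json(res$config, out("config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logs <- dplyr::bind_rows(
    dplyr::mutate(res$virus_rejections, role = "virus"),
    dplyr::mutate(res$host_rejections, role = "host")
  )
  readr::write_tsv(logs, out("rejection_log.tsv"))
  if (!is.null(res$gc)) {
    comp <- dplyr::left_join(
      res$gc, dplyr::select(res$pr2, "gene_id", "at_bias", "gc_bias"),
      by = "gene_id")
    readr::write_tsv(comp, out("gc_virus.tsv"), na = "NA")
    if (write_plots) {
      plot_pr2(res$pr2, file = out("pr2_plot.png"))
    }
    readr::write_tsv(pr2_data(res$pr2), out("pr2_coordinates.tsv"))
  }
  if (!is.null(res$gene_indices)) {
    readr::write_tsv(res$gene_indices, out("gene_indices_virus.tsv"),
                     na = "NA")
    readr::write_tsv(res$host_enc, out("enc_host.tsv"), na = "NA")
    gc3 <- gc_content(virus)
    readr::write_tsv(enc_gc3_data(res$gene_indices, gc3),
                     out("enc_gc3_coordinates.tsv"))
    if (write_plots) {
      plot_enc_gc3(res$gene_indices, gc3, file = out("enc_gc3_plot.png"))
    }
  }
  if (!is.null(res$rscu_virus)) {
    readr::write_tsv(rscu_wide(res$rscu_virus), out("rscu_virus.tsv"),
                     na = "NA")
    readr::write_tsv(rscu_wide(res$rscu_host), out("rscu_host.tsv"),
                     na = "NA")
    readr::write_tsv(res$sid, out("sid.tsv"))
  }
  if (!is.null(res$dinuc)) {
    readr::write_tsv(res$dinuc, out("dinuc_virus.tsv"), na = "NA")
  }
  invisible(res)
}

# long per-gene RSCU -> gene x codon matrix tibble
rscu_wide <- function(rscu_tbl) {
  tidyr::pivot_wider(rscu_tbl[, c("gene_id", "codon", "rscu")],
                     names_from = "codon", values_from = "rscu")
}

#' @export
print.codon_coadaptation <- function(x, ...) {
  cat("<codon_coadaptation>\n")
  cat(sprintf("  virus: %d genes (%s)\n", x$n_virus, x$config$virus_path))
  cat(sprintf("  host:  %d genes (%s)\n", x$n_host, x$config$host_path))
  cat(sprintf("  branches: %s\n", paste(x$config$analyses, collapse = ", ")))
  if (!is.null(x$sid)) {
    cat(sprintf("  SiD = %.4f (cosine similarity %.4f over %d codons)\n",
                x$sid$sid, x$sid$cosine_similarity, x$sid$n_codons))
  }
  if (!is.null(x$gene_indices)) {
    cat(sprintf("  virus gene indices: mean ENc %.2f, mean CAI %.3f, mean RCDI %.3f\n",
                mean(x$gene_indices$enc, na.rm = TRUE),
                mean(x$gene_indices$cai, na.rm = TRUE),
                mean(x$gene_indices$rcdi, na.rm = TRUE)))
  }
  invisible(x)
}

#' Tidy the per-gene results of a codon co-adaptation analysis
#'
#' @param x A `codon_coadaptation` object from [run_codon_analysis()].
#' @param ... Unused.
#' @return A tibble of per-virus-gene measures (whichever branches ran).
#' @exportS3Method generics::tidy
tidy.codon_coadaptation <- function(x, ...) {
  gc_part <- x$gc
  if (!is.null(gc_part) && !is.null(x$gene_indices)) {
    gc_part <- dplyr::select(gc_part, !dplyr::any_of("gc3"))
  }
  parts <- list(x$gene_indices, gc_part,
                if (!is.null(x$pr2)) {
                  dplyr::select(x$pr2, "gene_id", "at_bias", "gc_bias")
                })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0L) {
    return(tibble::tibble(gene_id = character(0)))
  }
  out <- purrr::reduce(parts, dplyr::full_join, by = "gene_id")
  dplyr::select(out, !dplyr::any_of(c("gc_overall", "gc1", "gc2")))
}

#' One-row summary of a codon co-adaptation analysis
#'
#' @inheritParams tidy.codon_coadaptation
#' @return A one-row tibble: gene counts, SiD, and virus-wide means of the
#'   per-gene indices (NA for branches that did not run).
#' @exportS3Method generics::glance
glance.codon_coadaptation <- function(x, ...) {
  gi <- x$gene_indices
  tibble::tibble(
    n_virus_genes = x$n_virus,
    n_host_genes = x$n_host,
    sid = if (!is.null(x$sid)) x$sid$sid else NA_real_,
    mean_enc = if (!is.null(gi)) mean(gi$enc, na.rm = TRUE) else NA_real_,
    mean_scuo = if (!is.null(gi)) mean(gi$scuo, na.rm = TRUE) else NA_real_,
    mean_cai = if (!is.null(gi)) mean(gi$cai, na.rm = TRUE) else NA_real_,
    mean_rcdi = if (!is.null(gi)) mean(gi$rcdi, na.rm = TRUE) else NA_real_
  )
}

#' Diagnostic plots for a codon co-adaptation analysis
#'
#' @param object A `codon_coadaptation` object.
#' @param type `"enc_gc3"` or `"pr2"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.codon_coadaptation <- function(object, type = c("enc_gc3", "pr2"),
                                        ...) {
  type <- match.arg(type)
  if (type == "enc_gc3") {
    if (is.null(object$gene_indices)) {
      stop("gene branch was not run; no ENc values to plot", call. = FALSE)
    }
    gc3 <- dplyr::select(object$gene_indices, "gene_id", "gc3")
    plot_enc_gc3(object$gene_indices, gc3)
  } else {
    if (is.null(object$pr2)) {
      stop("composition branch was not run; no PR2 coordinates", call. = FALSE)
    }
    plot_pr2(object$pr2)
  }
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
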