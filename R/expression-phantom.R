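#' Generate a synthetic two-batch expression matrix with planted DE genes
#'
#' Emulates a merged two-cohort log-expression matrix (e.g. two tumour
#' histologies profiled separately): per-gene baselines, an additive and
#' multiplicative per-gene batch effect for batch B, a group effect for a
#' planted set of differentially expressed genes, and Gaussian noise. A
#' glycolysis-style gene list is sampled so that it overlaps the planted DE
#' set by a configurable count, and one gene is designated the PD-L1
#' transcript stand-in (always planted up-regulated in the high group).
#'
#' Defaults mirror the study conditions: 5000 genes, 753-gene glycolysis
#' list, 62 planted DE genes (53 up, 9 down), 4 of them glycolytic.
#'
#' @param n_genes Number of genes.
#' @param n_samples Number of samples (split evenly between groups, and
#'   independently between batches A/B).
#' @param batch_shift Length-2: mean additive shift and scale multiplier for
#'   batch B (per-gene additive shifts are drawn N(shift, 0.3)).
#' @param de_spec List with \code{n_up}, \code{n_down}, \code{effect}
#'   (log-scale group effect magnitude).
#' @param n_glycolysis Size of the glycolysis gene list.
#' @param glyco_de_overlap How many planted DE genes the glycolysis list
#'   must contain.
#' @param noise_sd Residual SD on the log scale.
#' @param seed Integer seed.
#'
#' @return An object of class \code{synthetic_expression}: list with
#'   \code{log_expression} (genes x samples), \code{gene_ids},
#'   \code{batch}, \code{group}, \code{target_gene_id},
#'   \code{glycolysis_list}, \code{planted_de} (named vector of signed
#'   effects).
#' @export
generate_expression <- function(n_genes = 5000, n_samples = 120,
                                batch_shift = c(1.0, 1.5),
                                de_spec = list(n_up = 53, n_down = 9,
                                               effect = 2.0),
                                n_glycolysis = 753,
                                glyco_de_overlap = 4,
                                noise_sd = 0.5,
                                seed = 1L) {
  stop_if(n_genes < n_glycolysis,
          "n_genes must be at least the glycolysis list size")
  n_de <- de_spec$n_up + de_spec$n_down
  stop_if(glyco_de_overlap > min(n_de, n_glycolysis),
          "glyco_de_overlap exceeds the planted DE or glycolysis list size")
  n_group <- c(floor(n_samples / 2), ceiling(n_samples / 2))
  stop_if(min(n_group) < 3, "need at least 3 samples per group")
  set.seed(as.integer(seed))

  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  group <- rep(c("PD-L1-low", "PD-L1-high"), times = n_group)
  ## batches crossed with groups so batch is not confounded with group
  batch <- unlist(lapply(n_group, function(n)
    rep(c("A", "B"), length.out = n)))

  baseline <- stats::rnorm(n_genes, 6, 1.5)
  expr <- matrix(rep(baseline, n_samples), nrow = n_genes)

  ## planted group effects; target gene is always up in the high group
  planted <- numeric(0)
  if (n_de > 0) {
    de_idx <- sample.int(n_genes, n_de)
    eff <- c(rep(de_spec$effect, de_spec$n_up),
             rep(-de_spec$effect, de_spec$n_down))
    planted <- stats::setNames(eff, gene_ids[de_idx])
  }
  up_ids <- names(planted)[planted > 0]
  ## PD-L1 transcript stand-in: an up-regulated planted gene when one
  ## exists, otherwise an arbitrary (null) gene
  target <- if (length(up_ids)) up_ids[1] else gene_ids[1]
  hi <- group == "PD-L1-high"
  if (length(planted)) {
    expr[match(names(planted), gene_ids), hi] <-
      expr[match(names(planted), gene_ids), hi] + planted
  }

  ## batch B: per-gene additive shift and global scale inflation
  gamma <- stats::rnorm(n_genes, batch_shift[1], 0.3)
  noise <- matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd),
                  nrow = n_genes)
  inB <- batch == "B"
  noise[, inB] <- noise[, inB] * batch_shift[2]
  expr[, inB] <- expr[, inB] + gamma
  expr <- expr + noise
  dimnames(expr) <- list(gene_ids, sprintf("T%04d", seq_len(n_samples)))

  ## glycolysis list overlaps the planted DE set by exactly glyco_de_overlap
  de_ids <- names(planted)
  in_de <- if (glyco_de_overlap > 0) sample(de_ids, glyco_de_overlap) else character(0)
  pool <- setdiff(gene_ids, de_ids)
  glyco <- c(in_de, sample(pool, n_glycolysis - length(in_de)))
  glyco <- sample(glyco)

  structure(list(log_expression = expr, gene_ids = gene_ids,
                 batch = batch, group = group,
                 target_gene_id = target,
                 glycolysis_list = glyco,
                 planted_de = planted),
            class = "synthetic_expression")
}

#' Write a synthetic expression dataset to disk
#'
#' Expression TSV (genes x samples), sample annotation CSV (sample, batch,
#' group) and the glycolysis gene list as plain text.
#'
#' @param x A \code{synthetic_expression}.
#' @param dir Output directory.
#' @return Invisibly, the expression TSV path.
#' @export
write_expression <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_expression"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, "expression.tsv")
  utils::write.table(round(x$log_expression, 5), tsv, sep = "\t",
                     quote = FALSE, col.names = NA)
  utils::write.csv(data.frame(sample = colnames(x$log_expression),
                              batch = x$batch, group = x$group),
                   file.path(dir, "samples.csv"), row.names = FALSE)
  writeLines(x$glycolysis_list, file.path(dir, "glycolysis_genes.txt"))
  invisible(tsv)
}
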