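#' Simulation configuration
#'
#' Loads and validates a simulation configuration. `x` may be the name of a
#' shipped config (`"minimal"`, `"rankcurve"`, `"spin1like"`, `"ago2like"`,
#' `"pingpong"`), a path to a YAML file, or a config list. Shipped configs
#' live under `inst/extdata/configs/` and are plain data files.
#'
#' A config contains: `seed`; `genome` (`length`, `gc_content`, `chrom`);
#' `genes` (each with `gene_id`, `n_exons`, `exon_len` range, `intron_len`
#' range, `utr5_len`, `utr3_len`, `strand`) and/or a `gene_array` template
#' (`n`, `id_prefix`, plus the same fields) expanded into that many genes;
#' `clusters` (`cluster_id`, `length`, `strand`); `pgfs` (pseudogene
#' fragment specs: `pgf_id`, `source_gene`, `host_cluster`, `exon_range`,
#' `five_prime_truncation`, `divergence`, `tsd_length`, `orientation`,
#' `include_intron`); an optional `pgf_array` that plants one cluster+PGF
#' per `gene_array` gene with target weights from a `weights` scheme;
#' `pirna_sampling` (`total_reads`, `length_probs`, `u1_probability`,
#' `background_fraction`, `cluster_weights`, `pgf_fraction`,
#' `pingpong_fraction`); and `expression` (`effect_size_top`,
#' `effect_size_lower`, `sd`, `n_non_targets`).
#'
#' @param x config name, YAML path, or list.
#' @param seed optional seed override.
#' @return validated config list of class `sim_config`.
#' @export
sim_config <- function(x = "minimal", seed = NULL) {
  if (is.character(x)) {
    path <- x
    if (!file.exists(path)) {
      path <- system.file("extdata", "configs", paste0(x, ".yaml"),
                          package = "piswarm")
      if (!nzchar(path)) stop("sim_config: unknown config '", x, "'")
    }
    cfg <- yaml::read_yaml(path)
  } else {
    cfg <- x
  }
  if (!is.null(seed)) cfg$seed <- seed
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), !is.null(cfg$genome$length))
  cfg$genome$gc_content <- cfg$genome$gc_content %||% 0.45
  cfg$genome$chrom <- cfg$genome$chrom %||% "chr1"
  stopifnot(cfg$genome$gc_content >= 0, cfg$genome$gc_content <= 1)
  # expand gene_array templates into explicit gene specs
  genes <- cfg$genes %||% list()
  if (!is.null(cfg$gene_array)) {
    ga <- cfg$gene_array
    for (i in seq_len(ga$n_genes)) {
      g <- ga
      g$n_genes <- NULL
      g$id_prefix <- NULL
      g$gene_id <- sprintf("%s%03d", ga$id_prefix %||% "g", i)
      genes[[length(genes) + 1L]] <- g
    }
  }
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    stopifnot(!is.null(g$gene_id), g$n_exons >= 1)
    genes[[i]]$strand <- g$strand %||% "+"
    genes[[i]]$exon_len <- rep(as.integer(g$exon_len), length.out = 2L)
    genes[[i]]$intron_len <- rep(as.integer(g$intron_len %||% 200L), length.out = 2L)
    genes[[i]]$utr5_len <- as.integer(g$utr5_len %||% 100L)
    genes[[i]]$utr3_len <- as.integer(g$utr3_len %||% 300L)
  }
  cfg$genes <- genes
  clusters <- cfg$clusters %||% list()
  pgfs <- cfg$pgfs %||% list()
  cw <- cfg$pirna_sampling$cluster_weights
  if (!is.null(cfg$pgf_array)) {
    pa <- cfg$pgf_array
    w <- planted_weights(pa$weights, length(genes))
    cw <- list()
    for (i in seq_along(genes)) {
      cid <- sprintf("pic_%s", genes[[i]]$gene_id)
      clusters[[length(clusters) + 1L]] <-
        list(cluster_id = cid, length = as.integer(pa$cluster_length %||% 300L),
             strand = pa$cluster_strand %||% "+")
      pgfs[[length(pgfs) + 1L]] <-
        list(pgf_id = sprintf("pgf_%s", genes[[i]]$gene_id),
             source_gene = genes[[i]]$gene_id, host_cluster = cid,
             exon_range = as.integer(pa$exon_range),
             five_prime_truncation = as.integer(pa$five_prime_truncation %||% 0L),
             divergence = pa$divergence %||% 0,
             tsd_length = as.integer(pa$tsd_length %||% 10L),
             orientation = pa$orientation %||% "antisense",
             include_intron = isTRUE(pa$include_intron))
      cw[[cid]] <- w[i]
    }
  }
  for (i in seq_along(clusters)) {
    clusters[[i]]$strand <- clusters[[i]]$strand %||% "+"
    stopifnot(clusters[[i]]$length >= 200L)
  }
  for (i in seq_along(pgfs)) {
    p <- pgfs[[i]]
    stopifnot(length(p$exon_range) == 2L)
    if ((p$divergence %||% 0) >= 0.5) stop("sim_config: divergence >= 0.5 rejected")
    pgfs[[i]]$orientation <- p$orientation %||% "antisense"
    pgfs[[i]]$five_prime_truncation <- as.integer(p$five_prime_truncation %||% 0L)
    pgfs[[i]]$include_intron <- isTRUE(p$include_intron)
  }
  cfg$clusters <- clusters
  cfg$pgfs <- pgfs
  ps <- cfg$pirna_sampling %||% list()
  ps$total_reads <- as.integer(ps$total_reads %||% 10000L)
  if (is.null(ps$length_probs)) {
    ps$length_probs <- stats::setNames(
      c(0.05, 0.1, 0.2, 0.25, 0.2, 0.12, 0.08), 26:32)
  } else {
    ps$length_probs <- unlist(ps$length_probs)
  }
  ps$length_probs <- ps$length_probs / sum(ps$length_probs)
  ps$u1_probability <- ps$u1_probability %||% 0.75
  ps$background_fraction <- ps$background_fraction %||% 0.2
  ps$pgf_fraction <- ps$pgf_fraction %||% 0.8
  ps$pingpong_fraction <- ps$pingpong_fraction %||% 0
  rates <- c(ps$u1_probability, ps$background_fraction, ps$pgf_fraction,
             ps$pingpong_fraction)
  stopifnot(all(rates >= 0), all(rates <= 1))
  if (length(clusters)) {
    if (is.null(cw)) {
      cw <- as.list(stats::setNames(rep(1 / length(clusters), length(clusters)),
                                    vapply(clusters, `[[`, character(1), "cluster_id")))
    }
    wv <- unlist(cw)
    ps$cluster_weights <- wv / sum(wv)
  }
  cfg$pirna_sampling <- ps
  ex <- cfg$expression %||% list()
  ex$effect_size_top <- ex$effect_size_top %||% 1.0
  ex$effect_size_lower <- ex$effect_size_lower %||% 0.25
  ex$sd <- ex$sd %||% 0.5
  ex$n_non_targets <- as.integer(ex$n_non_targets %||% 300L)
  cfg$expression <- ex
  structure(cfg, class = "sim_config")
}

# Rank-weight vector for a planted target hierarchy. Scheme "zipf_mix":
# rank 1 takes `top1`; ranks 2..top_k follow a power law scaled so the top_k
# prefix accumulates exactly `top_coverage`; remaining ranks share the rest
# with the same power law.
planted_weights <- function(scheme, n) {
  if (is.null(scheme)) return(rep(1 / n, n))
  stopifnot(identical(scheme$type, "zipf_mix"), n > scheme$top_k)
  top1 <- scheme$top1
  k <- scheme$top_k
  cov <- scheme$top_coverage
  alpha <- scheme$alpha %||% 1.0
  w <- numeric(n)
  w[1] <- top1
  mid <- (2:k)^(-alpha)
  w[2:k] <- mid / sum(mid) * (cov - top1)
  tail <- ((k + 1):n)^(-alpha)
  w[(k + 1):n] <- tail / sum(tail) * (1 - cov)
  if (any(diff(w) > 1e-12)) {
    stop("planted_weights: weight vector not monotone decreasing; ",
         "increase n or decrease alpha so the planted rank prefix is real")
  }
  w
}
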