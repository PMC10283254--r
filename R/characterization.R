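# Molecular characterization: per-feature differential expression by
# linear models with BH-FDR, miRNA target-gene expansion, hypergeometric
# over-representation analysis, and enrichment-overlap summaries.

#' Differential expression between subtypes by linear models
#'
#' Ordinary least squares of every feature on a subtype-1 indicator
#' (optionally plus covariates), with a two-sided t-test on the subtype
#' coefficient and Benjamini-Hochberg adjustment within the modality. The
#' reported estimate is subtype 1 minus subtype 2 on the analysis scale;
#' direction (up/down) is assigned only to features with `q <
#' fdr_threshold`.
#'
#' @param block an [omics_block()] (or plain subjects x features matrix).
#' @param labels subtype labels (1/2), named or aligned to rows.
#' @param covariates optional data.frame of per-subject covariates,
#'   aligned to rows of the block.
#' @param fdr_threshold FDR significance threshold (default 0.05).
#' @return data.frame: `feature`, `modality`, `estimate`, `p`, `q`,
#'   `significant`, `direction` (`"up"`/`"down"`/`NA`).
#' @export
differential_expression <- function(block, labels, covariates = NULL,
                                    fdr_threshold = 0.05) {
  if (inherits(block, "omics_block")) {
    Y <- block$values; modality <- block$modality
  } else {
    Y <- as.matrix(block); modality <- NA_character_
  }
  labels <- as_labels(labels)
  if (!is.null(names(labels)) && !is.null(rownames(Y)))
    labels <- labels[rownames(Y)]
  grp_n <- table(labels)
  if (length(grp_n) < 2 || min(grp_n) < 2)
    stop("each subtype needs >= 2 subjects (singleton group)")
  if (min(grp_n) < 3)
    warning("subtype with < 3 subjects: estimates will be unstable")
  ind <- as.numeric(labels == 1)
  X <- cbind(intercept = 1, subtype1 = ind)
  if (!is.null(covariates)) {
    mm <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1,
                                                                     drop = FALSE]
    X <- cbind(X, mm)
  }
  keep <- apply(Y, 2, function(col) stats::sd(col) > 0)
  if (any(!keep))
    snf_log(sum(!keep), " zero-variance feature(s) skipped")
  Y <- Y[, keep, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("collinear design matrix")
  coefs <- qr.coef(qrX, Y)                    # p x F
  fitted <- X %*% coefs
  res <- Y - fitted
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  xtx_inv <- solve(crossprod(X))
  se <- sqrt(sigma2 * xtx_inv["subtype1", "subtype1"])
  est <- coefs["subtype1", ]
  tstat <- est / se
  p <- 2 * stats::pt(-abs(tstat), df)
  q <- stats::p.adjust(p, method = "BH")
  sig <- q < fdr_threshold
  out <- data.frame(feature = colnames(Y), modality = modality,
                    estimate = est, p = p, q = q, significant = sig,
                    direction = ifelse(sig, ifelse(est > 0, "up", "down"),
                                       NA_character_),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a miRNA -> target-gene map
#'
#' Two-column delimited file (mirna_id, gene_symbol). Empty target sets
#' are not retained.
#'
#' @param path file path.
#' @param delim delimiter.
#' @return Named list: miRNA id -> character vector of target genes.
#' @export
read_mirna_targets <- function(path, delim = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE)
  sp <- split(df[[2]], df[[1]])
  sp <- lapply(sp, unique)
  sp[lengths(sp) > 0]
}

#' Expand significant miRNAs to their target genes
#'
#' Union of validated target genes over significantly up-regulated
#' miRNAs and, separately, down-regulated miRNAs. miRNAs absent from the
#' map are counted and logged, not an error.
#'
#' @param de a [differential_expression()] result for the miRNA modality.
#' @param target_map named list miRNA -> target genes (see
#'   [read_mirna_targets()]).
#' @return List: `up` and `down` gene sets, `n_unmapped`.
#' @export
map_mirna_targets <- function(de, target_map) {
  if (length(target_map) == 0) stop("empty miRNA target map")
  pick <- function(dir) {
    ids <- de$feature[de$significant & de$direction == dir &
                        !is.na(de$direction)]
    missing <- setdiff(ids, names(target_map))
    list(genes = sort(unique(unlist(target_map[intersect(ids, names(target_map))]))),
         n_missing = length(missing))
  }
  up <- pick("up"); down <- pick("down")
  n_unmapped <- up$n_missing + down$n_missing
  if (n_unmapped > 0)
    snf_log(n_unmapped, " significant miRNA(s) absent from the target map; skipped")
  list(up = up$genes, down = down$genes, n_unmapped = n_unmapped)
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (name, description, genes...).
#' @return A `gene_set_collection` (see [gene_set_collection()]); the
#'   universe defaults to the union of all set members.
#' @export
read_gene_sets <- function(path) {
  sets <- fgsea::gmtPathways(path)
  gene_set_collection(sets)
}

#' Construct a gene-set collection
#'
#' @param sets named list: pathway -> character vector of gene symbols.
#' @param universe optional background gene universe; defaults to the
#'   union of all pathway members. Pathway members outside the universe
#'   are clipped with a log line.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (length(sets) == 0) stop("empty gene-set collection")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("all pathways must be named")
  sets <- lapply(sets, unique)
  if (any(lengths(sets) == 0)) stop("empty pathway in collection")
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets)))
  } else {
    universe <- unique(universe)
    clipped <- sum(vapply(sets, function(s) sum(!(s %in% universe)), 0L))
    if (clipped > 0)
      snf_log(clipped, " pathway member(s) outside the universe clipped")
    sets <- lapply(sets, intersect, universe)
    sets <- sets[lengths(sets) > 0]
    if (length(sets) == 0) stop("no pathway overlaps the universe")
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Hypergeometric over-representation analysis
#'
#' Right-tail hypergeometric test of each pathway's overlap with the query
#' gene set, against the collection's universe, with Benjamini-Hochberg
#' adjustment across pathways. Query genes outside the universe are
#' dropped with a warning. An empty query returns an empty result.
#'
#' @param query character vector of gene symbols.
#' @param collection a [gene_set_collection()].
#' @param fdr_threshold FDR threshold defining `enriched`.
#' @param direction free-text tag stored on the result (e.g. `"up"`).
#' @return data.frame: `pathway`, `overlap`, `pathway_size`, `query_size`,
#'   `universe_size`, `p`, `q`, `enriched`, `direction`.
#' @export
ora_hypergeometric <- function(query, collection, fdr_threshold = 0.05,
                               direction = NA_character_) {
  if (!inherits(collection, "gene_set_collection"))
    stop("collection must be a gene_set_collection")
  query <- unique(query)
  outside <- setdiff(query, collection$universe)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, collection$universe)
  }
  if (length(query) == 0)
    return(data.frame(pathway = character(), overlap = integer(),
                      pathway_size = integer(), query_size = integer(),
                      universe_size = integer(), p = numeric(), q = numeric(),
                      enriched = logical(), direction = character()))
  N <- length(collection$universe)
  m <- length(query)
  k <- vapply(collection$sets, function(s) length(intersect(s, query)), 0L)
  K <- lengths(collection$sets)
  p <- stats::phyper(k - 1, K, N - K, m, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(pathway = names(collection$sets), overlap = k,
                    pathway_size = K, query_size = m, universe_size = N,
                    p = p, q = q, enriched = q < fdr_threshold,
                    direction = direction, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$p, out$pathway), ]
}

#' Venn-region counts for named enrichment result sets
#'
#' All regionwise counts of the Venn partition of >= 2 named sets of
#' pathway names (singletons, pairwise, triple, ...), with the member
#' pathways per region.
#'
#' @param sets named list of character vectors (e.g. enriched pathway
#'   names per analysis); names must be unique.
#' @return data.frame: `region` (comma-joined set names), `n`, `members`.
#' @export
enrichment_overlap <- function(sets) {
  if (length(sets) < 2) stop("need >= 2 named sets")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("set names must be present and unique")
  nm <- names(sets)
  all_items <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) all_items %in% s,
                   logical(length(all_items)))
  if (length(all_items) == 1) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL, nm))
  rows <- list()
  for (mask in seq_len(2^length(nm) - 1)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_along(nm) - 1)))
    if (length(all_items) == 0) {
      items <- character()
    } else {
      sel <- rowSums(member[, inset, drop = FALSE]) == sum(inset) &
        rowSums(member[, !inset, drop = FALSE]) == 0
      items <- all_items[sel]
    }
    rows[[length(rows) + 1]] <- data.frame(
      region = paste(nm[inset], collapse = ","),
      n = length(items),
      members = paste(items, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
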