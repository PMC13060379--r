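#' netcog: structural brain networks and general cognitive function
#'
#' Tools for the full analysis chain linking structural connectomes to a
#' latent factor of general cognitive function (g): cross-cohort reference
#' network construction by consistency thresholding, weighted graph metrics,
#' FIML confirmatory factor analysis of g, MIMIC-style structural regression,
#' REML random-effects meta-analysis with FDR control, and edge-wise
#' composite prediction, together with a multi-cohort synthetic-data
#' generator for end-to-end testing.
#'
#' @useDynLib netcog, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef cor dnorm lm logLik na.omit optim p.adjust pnorm
#'   predict qnorm quantile residuals rnorm runif sd var rbinom rlnorm plogis
#'   uniroot setNames complete.cases
#' @importFrom utils read.csv write.csv head
#' @keywords internal
"_PACKAGE"

.netcog_env <- new.env(parent = emptyenv())

#' Node atlas for the 85-region parcellation
#'
#' Returns the packaged atlas table defining the canonical node order used by
#' every matrix and mask in the package: 34 left cortical regions
#' (Desikan-Killiany, alphabetical), 34 right cortical, 8 left and 8 right
#' subcortical structures, and the brainstem last (index 84). Indices are
#' 0-based everywhere in files and APIs.
#'
#' @return A data.frame with columns `index` (0..84), `name`, `hemisphere`
#'   (`left`/`right`/`midline`), `lobe`, and `pair_index` (shared id for the
#'   42 bilateral homologue pairs; `NA` for the brainstem).
#' @export
dk_atlas <- function() {
  if (is.null(.netcog_env$atlas)) {
    path <- system.file("extdata", "atlas_dk85.csv", package = "netcog")
    atlas <- read.csv(path, stringsAsFactors = FALSE)
    stopifnot(nrow(atlas) == 85, !anyDuplicated(atlas$name),
              sum(atlas$hemisphere == "midline") == 1)
    .netcog_env$atlas <- atlas
  }
  .netcog_env$atlas
}

#' All node pairs of the atlas in canonical order
#'
#' The canonical edge order is `i` ascending then `j` ascending over 0-based
#' unordered pairs `i < j`; all edge-level vectors and matrices in the
#' package are aligned to it.
#'
#' @param n_nodes number of nodes (default 85).
#' @return data.frame with columns `i`, `j` (0-based, i < j) and `lin`, the
#'   1-based linear index of element `[i+1, j+1]` in an `n_nodes` square
#'   matrix.
#' @export
all_edges <- function(n_nodes = 85L) {
  key <- paste0("edges", n_nodes)
  if (is.null(.netcog_env[[key]])) {
    ij <- t(utils::combn(seq_len(n_nodes) - 1L, 2L))
    .netcog_env[[key]] <- data.frame(i = ij[, 1], j = ij[, 2],
                                     lin = ij[, 1] + 1L + ij[, 2] * n_nodes)
  }
  .netcog_env[[key]]
}

# ---- edge masks -----------------------------------------------------------

#' Construct an edge mask
#'
#' An edge mask is the set of unordered node pairs defining a reference
#' network. Pairs are stored 0-based with `i < j`, deduplicated, and sorted
#' in canonical order (`i` ascending, then `j`).
#'
#' @param i,j integer vectors of node indices (0-based), or `i` may be a
#'   two-column data.frame/matrix of pairs.
#' @param provenance free-text label recording how the mask was made.
#' @param n_nodes atlas size.
#' @return An object of class `edge_mask`: a data.frame with columns `i`,
#'   `j` plus attributes `provenance` and `n_nodes`.
#' @export
edge_mask <- function(i, j = NULL, provenance = "", n_nodes = 85L) {
  if (is.null(j)) {
    m <- as.data.frame(i)
    i <- m[[1]]; j <- m[[2]]
  }
  i <- as.integer(i); j <- as.integer(j)
  if (length(i) != length(j)) stop("i and j must have equal length")
  if (any(i == j)) stop("self-pairs are not allowed in an edge mask")
  lo <- pmin(i, j); hi <- pmax(i, j)
  if (length(lo) && (min(lo) < 0 || max(hi) >= n_nodes))
    stop("edge indices outside the atlas (expected 0..", n_nodes - 1, ")")
  df <- unique(data.frame(i = lo, j = hi))
  df <- df[order(df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("edge_mask", "data.frame"),
            provenance = provenance, n_nodes = n_nodes)
}

#' @method print edge_mask
#' @export
print.edge_mask <- function(x, ...) {
  cat("Edge mask:", nrow(x), "edges over", attr(x, "n_nodes"), "nodes",
      sprintf("(density %.3f)\n", mask_density(x)))
  if (nzchar(attr(x, "provenance")))
    cat("Provenance:", attr(x, "provenance"), "\n")
  invisible(x)
}

#' Read / write an edge mask
#'
#' Masks are CSV files with header `i,j`, 0-based indices, `i < j`, sorted.
#'
#' @param path file path.
#' @param n_nodes atlas size.
#' @return `read_edge_mask` returns an `edge_mask`.
#' @export
read_edge_mask <- function(path, n_nodes = 85L) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("i", "j") %in% names(df))) stop("mask file must have columns i,j")
  edge_mask(df$i, df$j, provenance = paste0("file:", basename(path)),
            n_nodes = n_nodes)
}

#' @rdname read_edge_mask
#' @param mask an `edge_mask`.
#' @export
write_edge_mask <- function(mask, path) {
  write.csv(data.frame(i = mask$i, j = mask$j), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Density of an edge mask
#'
#' Fraction of all possible node pairs (`n(n-1)/2`, 3570 for 85 nodes)
#' present in the mask.
#'
#' @param m an `edge_mask`.
#' @return a fraction in `[0, 1]`.
#' @export
mask_density <- function(m) {
  n <- attr(m, "n_nodes")
  nrow(m) / (n * (n - 1) / 2)
}

# logical n x n matrix marking mask edges (both triangles)
mask_matrix <- function(m) {
  n <- attr(m, "n_nodes")
  M <- matrix(FALSE, n, n)
  M[cbind(m$i + 1L, m$j + 1L)] <- TRUE
  M[cbind(m$j + 1L, m$i + 1L)] <- TRUE
  M
}

# rows of all_edges() corresponding to mask edges
mask_rows <- function(m) {
  n <- attr(m, "n_nodes")
  match(m$i + 1L + m$j * n, all_edges(n)$lin)
}

# ---- connectomes ----------------------------------------------------------

.weightings <- c("SC", "FA", "MD", "SD")

#' Construct a connectome
#'
#' A participant-level weighted network: a symmetric nonnegative square
#' matrix with zero diagonal over the atlas nodes. FA entries must lie in
#' `[0, 1]`; MD is carried in units of 1e-3 mm^2/s.
#'
#' @param W square numeric matrix.
#' @param weighting one of `"SC"`, `"FA"`, `"MD"`, `"SD"`.
#' @param participant_id identifier.
#' @param tol absolute asymmetry tolerance; matrices within it are
#'   symmetrised from the upper triangle.
#' @return object of class `connectome` (the matrix, with attributes).
#' @export
connectome <- function(W, weighting = "SC", participant_id = "p1",
                       tol = 1e-9) {
  weighting <- match.arg(weighting, .weightings)
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("connectome matrix must be square")
  dev <- max(abs(W - t(W)))
  if (dev > tol)
    stop(sprintf("asymmetric connectome (max deviation %.3g > tol %.3g)",
                 dev, tol))
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  diag(W) <- 0
  if (any(W < 0)) stop("negative edge weight")
  if (weighting == "FA" && any(W > 1)) stop("FA weights must be <= 1")
  dimnames(W) <- NULL
  structure(W, class = c("connectome", "matrix", "array"),
            weighting = weighting, participant_id = participant_id)
}

#' @method print connectome
#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("Connectome [%s] participant %s: %d nodes, %d edges\n",
              attr(x, "weighting"), attr(x, "participant_id"), nrow(x),
              sum(x[upper.tri(x)] > 0)))
  invisible(x)
}

#' Read / write a connectome file
#'
#' Two formats are accepted: a dense delimited matrix (TSV default, comma
#' accepted; 85 rows x 85 columns, no header) or a long-format CSV with
#' header `participant_id,i,j,weight` (0-based indices; entries mirrored to
#' both triangles, unlisted pairs zero).
#'
#' @param path file path.
#' @param weighting edge weighting of the stored matrix.
#' @param participant_id identifier (overridden by the long format's column).
#' @param n_nodes atlas size.
#' @return a `connectome`.
#' @export
read_connectome <- function(path, weighting = "SC", participant_id = NULL,
                            n_nodes = 85L) {
  first <- readLines(path, n = 1L)
  if (grepl("participant_id", first, fixed = TRUE)) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("participant_id", "i", "j", "weight")
    if (!all(need %in% names(df)))
      stop("long format requires columns participant_id,i,j,weight")
    pid <- unique(df$participant_id)
    if (length(pid) != 1) stop("long-format file must hold one participant")
    W <- matrix(0, n_nodes, n_nodes)
    W[cbind(df$i + 1L, df$j + 1L)] <- df$weight
    W[cbind(df$j + 1L, df$i + 1L)] <- df$weight
    return(connectome(W, weighting, pid))
  }
  sep <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
  W <- as.matrix(read.table(path, sep = sep, header = FALSE))
  if (is.null(participant_id))
    participant_id <- sub("\\.[^.]*$", "", basename(path))
  connectome(W, weighting, participant_id)
}

#' @rdname read_connectome
#' @param c a `connectome`.
#' @param digits significant digits used when serialising weights.
#' @export
write_connectome <- function(c, path, digits = 17) {
  m <- unclass(c)
  attributes(m) <- list(dim = dim(m))
  write.table(format(m, digits = digits, trim = TRUE, scientific = TRUE),
              path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Apply an edge mask to a connectome
#'
#' Entries outside the mask are set to zero; entries inside it (including
#' zeros) are unchanged. Idempotent.
#'
#' @param c a `connectome` (or plain symmetric matrix).
#' @param m an `edge_mask`.
#' @return the masked connectome.
#' @export
apply_mask <- function(c, m) {
  keep <- mask_matrix(m)
  if (nrow(keep) != nrow(c)) stop("mask and connectome atlas sizes differ")
  out <- unclass(c)
  out[!keep] <- 0
  attributes(out) <- attributes(c)
  out
}

#' Streamline density: volume-normalised streamline counts
#'
#' Divides each streamline count by the summed grey-matter volumes of the
#' two endpoint regions: `SD[i,j] = SC[i,j] / (vol[i] + vol[j])`.
#'
#' @param c an SC-weighted `connectome`.
#' @param vol positive numeric vector of region volumes (mm^3), one per node.
#' @return an SD-weighted `connectome` (streamlines per mm^3).
#' @export
streamline_density <- function(c, vol) {
  if (attr(c, "weighting") != "SC")
    stop("streamline_density expects an SC-weighted connectome")
  if (length(vol) != nrow(c)) stop("one volume per node required")
  if (any(vol <= 0)) stop("region volumes must be positive")
  denom <- outer(vol, vol, "+")
  out <- unclass(c) / denom
  diag(out) <- 0
  connectome(out, "SD", attr(c, "participant_id"))
}
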