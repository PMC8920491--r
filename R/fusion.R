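#' Run a patch classifier under the patch-probability protocol
#'
#' A classifier is any function taking a list of native-resolution RGB
#' patch arrays and returning one class-probability vector per patch
#' (rows of a matrix, columns in the pipeline's class order). Vectors are
#' validated: nonnegative entries summing to 1 within 1e-6.
#'
#' @param classifier Function `patches -> numeric matrix (n x K)`.
#' @param patches List of RGB patch arrays.
#' @param n_classes Expected number of classes K.
#' @return Numeric matrix `length(patches) x n_classes`; rows sum to 1.
#' @export
classify_patches <- function(classifier, patches, n_classes) {
  if (!length(patches)) return(matrix(numeric(0), 0L, n_classes))
  p <- classifier(patches)
  p <- as.matrix(p)
  if (nrow(p) != length(patches) || ncol(p) != n_classes)
    stop("classifier protocol violation: expected ", length(patches), " x ",
         n_classes, " probability matrix, got ", nrow(p), " x ", ncol(p))
  if (any(!is.finite(p)) || any(p < -1e-9))
    stop("classifier protocol violation: probabilities must be finite and >= 0")
  if (any(abs(rowSums(p) - 1) > 1e-6))
    stop("classifier protocol violation: probability rows must sum to 1")
  p
}

#' Softmax fusion of patch probabilities
#'
#' The superpixel's probability vector is the mean of its patch softmax
#' vectors, `(sum_n p_n) / N`; the fused label is the argmax over classes
#' (ties broken towards the lowest class index).
#'
#' @param probs Numeric matrix (patches x classes), rows summing to 1.
#' @return List with `label` (integer class index) and `mean_vector`.
#' @export
fuse <- function(probs) {
  probs <- as.matrix(probs)
  if (!nrow(probs)) stop("cannot fuse an empty probability set")
  mv <- colMeans(probs)
  list(label = which.max(mv), mean_vector = mv)
}

#' Vote-difference confidence
#'
#' Each patch votes for the argmax of its probability vector (ties to the
#' lowest class index). The confidence is the difference between the top
#' two per-class vote counts divided by the number of patches,
#' `(v1 - v2) / N`; with a single represented class `v2 = 0`. Bounded in
#' `[0, 1]`: 1 iff unanimous, 0 iff the top two classes tie.
#'
#' @param probs Numeric matrix (patches x classes).
#' @return Scalar confidence in `[0, 1]`.
#' @export
vote_confidence <- function(probs) {
  probs <- as.matrix(probs)
  if (!nrow(probs)) stop("cannot compute confidence of an empty set")
  votes <- apply(probs, 1L, which.max)
  counts <- sort(tabulate(votes, ncol(probs)), decreasing = TRUE)
  v1 <- counts[1]
  v2 <- if (length(counts) > 1L) counts[2] else 0L
  (v1 - v2) / nrow(probs)
}

#' Fuse patch classifications into superpixel labels
#'
#' Runs [fuse()] and [vote_confidence()] per superpixel and tracks status:
#' `LABELED` for superpixels with at least one classified patch,
#' `UNCLASSIFIED` for tissue superpixels with none, `BACKGROUND` for
#' background superpixels.
#'
#' @param sample A `patch_sample` (rows = selected patches).
#' @param probs Probability matrix, one row per row of `sample`.
#' @param spmap The `superpixel_map` (for ids and background set).
#' @param class_names Character vector of class names (length K).
#' @return A `superpixel_labeling`: data.frame with columns `id`, `label`,
#'   `N`, `confidence`, `status`, plus attribute `mean_probs`
#'   (ids x K matrix of fused vectors, NA rows when unclassified).
#' @export
fuse_superpixels <- function(sample, probs, spmap, class_names) {
  K <- length(class_names)
  ids <- seq_along(spmap$sizes)
  mean_probs <- matrix(NA_real_, length(ids), K,
                       dimnames = list(ids, class_names))
  lab <- rep(NA_integer_, length(ids))
  nn <- integer(length(ids))
  conf <- rep(NA_real_, length(ids))
  status <- rep("UNCLASSIFIED", length(ids))
  status[spmap$background_ids] <- "BACKGROUND"
  for (id in unique(sample$superpixel_id)) {
    rows <- which(sample$superpixel_id == id)
    p <- probs[rows, , drop = FALSE]
    f <- fuse(p)
    lab[id] <- f$label
    mean_probs[id, ] <- f$mean_vector
    nn[id] <- length(rows)
    conf[id] <- vote_confidence(p)
    status[id] <- "LABELED"
  }
  out <- data.frame(id = ids, label = lab, N = nn,
                    confidence = conf, status = status)
  structure(out, mean_probs = mean_probs, class_names = class_names,
            class = c("superpixel_labeling", "data.frame"))
}

#' Reject low-confidence superpixels
#'
#' Sets status `REJECTED` for labelled superpixels whose vote-difference
#' confidence is strictly below `threshold` (a confidence exactly equal to
#' the threshold is kept). Labels of rejected superpixels are retained in
#' the table but excluded from rendered class maps and evaluation.
#'
#' @param labeling A `superpixel_labeling`.
#' @param threshold Rejection threshold in `[0, 1]` (default 0.1).
#' @return The labelling with updated `status`.
#' @export
apply_rejection <- function(labeling, threshold = 0.1) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  rej <- labeling$status == "LABELED" & labeling$confidence < threshold
  labeling$status[rej] <- "REJECTED"
  labeling
}

#' Render a per-pixel class map from superpixel labels
#'
#' Every pixel takes its superpixel's fused class code; background
#' superpixels (and label-0 pixels outside the bounding box) render as the
#' BACKGROUND sentinel, rejected superpixels as REJECTED and unclassified
#' ones as UNCLASSIFIED.
#'
#' @param spmap A `superpixel_map`.
#' @param labeling A `superpixel_labeling` covering all ids of `spmap`.
#' @param mpp Microns per pixel of the analysis plane (carried on the map).
#' @return A `class_map`: list with `codes` (integer matrix), `legend`
#'   (class names for codes 1..K), `mpp`.
#' @export
render_class_map <- function(spmap, labeling, mpp = NA_real_) {
  n <- length(spmap$sizes)
  if (nrow(labeling) < n || !all(seq_len(n) %in% labeling$id))
    stop("labeling is missing superpixel ids present in the map")
  sent <- sentinel_codes()
  code <- integer(n)
  st <- labeling$status[match(seq_len(n), labeling$id)]
  lb <- labeling$label[match(seq_len(n), labeling$id)]
  code[st == "LABELED"] <- lb[st == "LABELED"]
  code[st == "BACKGROUND"] <- sent[["BACKGROUND"]]
  code[st == "REJECTED"] <- sent[["REJECTED"]]
  code[st == "UNCLASSIFIED"] <- sent[["UNCLASSIFIED"]]
  codes <- matrix(sent[["BACKGROUND"]], nrow(spmap$labels), ncol(spmap$labels))
  inb <- spmap$labels > 0L
  codes[inb] <- code[spmap$labels[inb]]
  structure(list(codes = codes, legend = attr(labeling, "class_names"),
                 mpp = mpp),
            class = "class_map")
}

#' Construct a class map directly from a code raster
#'
#' @param codes Integer matrix of class codes and sentinels.
#' @param legend Class names for codes `1..K`.
#' @param mpp Microns per pixel.
#' @return A `class_map`.
#' @export
class_map <- function(codes, legend, mpp = NA_real_) {
  structure(list(codes = codes, legend = legend, mpp = mpp),
            class = "class_map")
}
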