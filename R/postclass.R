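#' Post-classification configuration
#'
#' Parameters of the three spatial clean-up operators applied to a classified
#' map. The defaults are the settings used on the lake imagery: majority
#' analysis with a 3x3 kernel and centre pixel weight 1; sieve at
#' 4-connectivity with minimum component size 2 (i.e. isolated single pixels
#' are removed); clump with size 3.
#'
#' @param majority_kernel odd kernel width >= 3 for the majority filter.
#' @param center_weight vote weight of the centre pixel (positive integer).
#' @param sieve_connectivity 4 or 8.
#' @param sieve_min_size components smaller than this become unclassified.
#' @param clump_size structuring-element width for morphological closing.
#' @param operator_order the sequence of operators applied by
#'   [apply_postclassification()].
#' @return A `postclass_config` object.
#' @export
postclass_config <- function(majority_kernel = 3, center_weight = 1,
                             sieve_connectivity = 4, sieve_min_size = 2,
                             clump_size = 3,
                             operator_order = c("majority", "sieve", "clump")) {
  if (majority_kernel < 3 || majority_kernel %% 2 == 0) {
    stopf("majority_kernel must be an odd integer >= 3")
  }
  if (center_weight < 1) stopf("center_weight must be a positive integer")
  if (!sieve_connectivity %in% c(4, 8)) stopf("sieve_connectivity must be 4 or 8")
  if (sieve_min_size < 1) stopf("sieve_min_size must be >= 1")
  if (clump_size < 1) stopf("clump_size must be >= 1")
  if (!all(operator_order %in% c("majority", "sieve", "clump"))) {
    stopf("operator_order entries must be majority, sieve or clump")
  }
  structure(list(majority_kernel = as.integer(majority_kernel),
                 center_weight = as.integer(center_weight),
                 sieve_connectivity = as.integer(sieve_connectivity),
                 sieve_min_size = as.integer(sieve_min_size),
                 clump_size = as.integer(clump_size),
                 operator_order = operator_order),
            class = "postclass_config")
}

# Windowed vote counts: votes[[l + 1]][r, c] = weighted count of label l in
# the kernel window centred at (r, c). Windows are clipped at image borders
# (out-of-image pixels cast no vote). Label 0 votes like any other label.
label_votes <- function(labels, kernel, center_weight, present) {
  h <- kernel %/% 2
  votes <- vector("list", length(present))
  names(votes) <- as.character(present)
  for (i in seq_along(present)) {
    ind <- (labels == present[i]) * 1L
    s <- matrix(0L, nrow(labels), ncol(labels))
    for (dr in -h:h) for (dc in -h:h) s <- s + shift_matrix(ind, dr, dc)
    votes[[i]] <- s + (center_weight - 1L) * ind
  }
  votes
}

#' Majority/minority analysis
#'
#' Replaces spurious isolated pixels with the class value held by the
#' majority of the pixels in the kernel window. The centre pixel's own label
#' is counted `center_weight` times; windows are clipped at image borders;
#' unclassified (0) participates in the vote like any other label. On a tie
#' for the top vote that includes the centre's label, the centre keeps its
#' label; a tie not involving the centre goes to the lowest class id.
#' `mode = "minority"` instead assigns the label with the fewest (nonzero)
#' votes in the window, with the same tie rules.
#'
#' @param map a [class_map()].
#' @param kernel odd kernel width (default 3).
#' @param center_weight centre pixel vote weight (default 1).
#' @param mode `"majority"` (default) or `"minority"`.
#' @return A [class_map()].
#' @export
majority_minority_filter <- function(map, kernel = 3, center_weight = 1,
                                     mode = c("majority", "minority")) {
  stopifnot(inherits(map, "class_map"))
  mode <- match.arg(mode)
  if (kernel %% 2 == 0) stopf("kernel must be odd")
  if (kernel < 1) stopf("kernel must be positive")
  if (center_weight < 1) stopf("center_weight must be a positive integer")
  present <- sort(unique(as.vector(map)))
  votes <- label_votes(unclass(map), as.integer(kernel),
                       as.integer(center_weight), present)
  if (mode == "majority") {
    best <- Reduce(pmax, votes)
  } else {
    pos <- lapply(votes, function(v) ifelse(v > 0, v, Inf))
    best <- Reduce(pmin, pos)
    votes <- pos
  }
  out <- unclass(map)
  # centre label keeps on ties it participates in
  centre_vote <- matrix(0, nrow(map), ncol(map))
  for (i in seq_along(present)) {
    sel <- unclass(map) == present[i]
    centre_vote[sel] <- votes[[i]][sel]
  }
  assigned <- centre_vote == best
  for (i in seq_along(present)) {     # ascending label order = lowest id wins
    w <- !assigned & (votes[[i]] == best)
    out[w] <- present[i]
    assigned <- assigned | w
  }
  class_map(out, map_scheme(map))
}

#' Sieve: remove sub-minimum connected components
#'
#' Computes connected components of equal nonzero labels at the given pixel
#' connectivity and sets components smaller than `min_size` to unclassified
#' (0); all other pixels are untouched. This is the documented source of the
#' occasional stray unclassified pixel in otherwise fully classified maps.
#'
#' @param map a [class_map()].
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent).
#' @param min_size minimum surviving component size in pixels (default 2).
#' @return A [class_map()].
#' @export
sieve_classes <- function(map, connectivity = 4, min_size = 2) {
  stopifnot(inherits(map, "class_map"))
  if (!connectivity %in% c(4, 8)) stopf("connectivity must be 4 or 8")
  if (min_size < 1) stopf("min_size must be >= 1")
  if (min_size == 1) return(map)
  lab <- unclass(map)
  h <- nrow(lab); w <- ncol(lab)
  edge_pairs <- function(dr, dc) {
    rs <- seq_len(h - max(dr, 0)); if (dr < 0) rs <- rs[rs > -dr]
    cs <- seq_len(w - max(dc, 0)); if (dc < 0) cs <- cs[cs > -dc]
    a <- outer(rs, (cs - 1) * h, `+`)                     # linear index (r, c)
    b <- outer(rs + dr, (cs + dc - 1) * h, `+`)
    same <- lab[a] == lab[b] & lab[a] != 0L
    cbind(a[same], b[same])
  }
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  ep <- do.call(rbind, lapply(offs, function(o) edge_pairs(o[1], o[2])))
  g <- igraph::make_empty_graph(n = h * w, directed = FALSE)
  if (nrow(ep)) g <- igraph::add_edges(g, t(ep))
  comp <- igraph::components(g)
  small <- comp$csize[comp$membership] < min_size & as.vector(lab) != 0L
  lab[matrix(small, h, w)] <- 0L
  class_map(lab, map_scheme(map))
}

# Binary dilation / erosion by a size x size square structuring element whose
# origin is the centre cell (upper-left biased for even sizes). Outside the
# image the mask is padded with background (FALSE).
se_offsets <- function(size) {
  lo <- -(size %/% 2)
  off <- lo:(size - 1 + lo)
  expand.grid(dr = off, dc = off)
}

binary_dilate <- function(mask, size) {
  off <- se_offsets(size)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off))) {
    out <- out | shift_matrix(mask, -off$dr[i], -off$dc[i], fill = FALSE)
  }
  out
}

binary_erode <- function(mask, size) {
  off <- se_offsets(size)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off))) {
    out <- out & shift_matrix(mask, off$dr[i], off$dc[i], fill = FALSE)
  }
  out
}

#' Clump: merge adjacent same-class areas
#'
#' Applies a morphological closing (dilate then erode, square structuring
#' element of width `size`) to each class's binary mask, merging nearby
#' fragments of the same class across thin gaps. Classes are processed in
#' descending order of pixel count; pixels gained by a closing adopt the
#' class only where the input map is unclassified (0) or holds a class
#' processed earlier in the order, and a later gain overrides an earlier one.
#' Originally labelled pixels of classes not yet processed are never
#' overwritten, and closing never removes a class's own pixels.
#'
#' @param map a [class_map()].
#' @param size structuring-element width >= 1 (default 3).
#' @return A [class_map()].
#' @export
clump_classes <- function(map, size = 3) {
  stopifnot(inherits(map, "class_map"))
  if (size < 1) stopf("size must be >= 1")
  input <- unclass(map)
  out <- input
  counts <- table(factor(as.vector(input), levels = map_scheme(map)$id))
  order_ids <- as.integer(names(sort(counts, decreasing = TRUE)))
  order_ids <- order_ids[counts[as.character(order_ids)] > 0]
  earlier <- integer(0)
  for (k in order_ids) {
    mask <- input == k
    closed <- binary_erode(binary_dilate(mask, size), size)
    gain <- closed & !mask
    allowed <- gain & (input == 0L | matrix(input %in% earlier, nrow(input)))
    out[allowed] <- k
    earlier <- c(earlier, k)
  }
  class_map(out, map_scheme(map))
}

#' Apply the post-classification chain
#'
#' Runs the configured operators in `operator_order` (default majority ->
#' sieve -> clump, the order in which they are meant to correct a raw
#' classification). The number of pixels changed by each step is recorded in
#' the `"changes"` attribute of the result and optionally messaged.
#'
#' @param map a [class_map()].
#' @param config a [postclass_config()].
#' @param verbose message per-step changed-pixel counts.
#' @return A [class_map()] with attribute `changes` (named integer vector).
#' @export
apply_postclassification <- function(map, config = postclass_config(),
                                     verbose = FALSE) {
  stopifnot(inherits(map, "class_map"), inherits(config, "postclass_config"))
  out <- map
  changes <- stats::setNames(integer(length(config$operator_order)),
                             config$operator_order)
  for (op in config$operator_order) {
    nxt <- switch(op,
      majority = majority_minority_filter(out, config$majority_kernel,
                                          config$center_weight),
      sieve = sieve_classes(out, config$sieve_connectivity, config$sieve_min_size),
      clump = clump_classes(out, config$clump_size)
    )
    changes[op] <- sum(unclass(nxt) != unclass(out))
    if (verbose) message(sprintf("%s: %d pixels changed", op, changes[op]))
    out <- nxt
  }
  attr(out, "changes") <- changes
  out
}
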