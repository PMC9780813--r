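# Labeled image dataset assembly: horizontal flip and mild contrast
# enhancement for minority-class augmentation, duplication for any
# remaining deficit, and a seeded stratified train/validation split.

#' Horizontal flip of a grayscale image
#'
#' Reverses the column order; an involution that preserves shape and
#' value range.
#'
#' @param img Integer image matrix.
#' @return Flipped image matrix.
#' @export
augmentFlip <- function(img) {
  img[, rev(seq_len(ncol(img))), drop = FALSE]
}

#' Contrast enhancement about mid-gray
#'
#' `pixel -> clip(128 + factor * (pixel - 128), 0, 255)`, rounded half away
#' from zero. The default factor 1.2 is deliberately mild so augmented
#' copies stay close to their originals.
#'
#' @param img Integer image matrix (0..255).
#' @param factor Contrast gain (> 0); 1 is the identity.
#' @return Adjusted image matrix.
#' @export
augmentContrast <- function(img, factor = 1.2) {
  if (factor <= 0) stop("contrast factor must be > 0")
  v <- 128 + factor * (img - 128)
  # round half away from zero (values are non-negative before clipping at 0,
  # so this is floor(v + 0.5) on the clipped range)
  out <- floor(pmin(pmax(v, 0), 255) + 0.5)
  matrix(as.integer(pmin(out, 255)), nrow(img), ncol(img))
}

#' Balance classes by augmentation and duplication
#'
#' Leaves the majority class untouched and fills the minority deficit in a
#' fixed order: horizontally flipped copies of minority originals, then
#' contrast-enhanced copies, then seeded-random duplicates of minority
#' originals. Augmented copies always derive from original items, never
#' from other augmented copies.
#'
#' @param set A [LabeledImageSet-class] containing both classes.
#' @param seed Integer seed for duplicate selection.
#' @param contrastFactor Gain for [augmentContrast()].
#' @return A balanced [LabeledImageSet-class]; added items are appended
#'   with provenance `flip`, `contrast` or `duplicate`.
#' @export
balanceClasses <- function(set, seed = 1, contrastFactor = 1.2) {
  meta <- set@meta
  counts <- table(meta$class)
  if (length(counts) < 2L)
    stop("both classes must be present; found only: ",
         paste(names(counts), collapse = ", "))
  if (length(unique(counts)) == 1L) return(set)
  minority <- names(which.min(counts))
  deficit <- max(counts) - min(counts)
  minIdx <- which(meta$class == minority & meta$provenance == "original")
  if (!length(minIdx)) minIdx <- which(meta$class == minority)

  takeFrom <- function(n, pool) pool[seq_len(min(n, length(pool)))]
  newImages <- list(); newMeta <- meta[0, ]
  add <- function(idx, fun, prov) {
    for (i in idx) {
      newImages[[length(newImages) + 1L]] <<- fun(set@images[[i]])
      newMeta[nrow(newMeta) + 1L, ] <<- list(meta$id[i], meta$class[i], prov)
    }
  }
  flips <- takeFrom(deficit, minIdx)
  add(flips, augmentFlip, "flip")
  remaining <- deficit - length(flips)
  contrasts <- takeFrom(remaining, minIdx)
  add(contrasts, function(im) augmentContrast(im, contrastFactor), "contrast")
  remaining <- remaining - length(contrasts)
  if (remaining > 0L) {
    dups <- .withSeed(seed, sample(minIdx, remaining, replace = TRUE))
    add(dups, identity, "duplicate")
  }
  new("LabeledImageSet", images = c(set@images, newImages),
      meta = rbind(meta, newMeta))
}

#' Train/validation split specification
#'
#' @param fraction Validation fraction, strictly between 0 and 1.
#' @param seed Integer seed.
#' @param stratified Stratify by class (default `TRUE`).
#' @return List of class `"SplitSpec"`.
#' @export
splitSpec <- function(fraction = 0.2, seed = 1, stratified = TRUE) {
  if (fraction <= 0 || fraction >= 1)
    stop("validation fraction must be in (0, 1)")
  structure(list(fraction = fraction, seed = as.integer(seed),
                 stratified = stratified), class = "SplitSpec")
}

#' Split an image set into train and validation subsets
#'
#' Seeded, disjoint, exhaustive; with `stratified = TRUE` the validation
#' fraction is drawn per class (`round(n_class * fraction)` items each).
#'
#' @param set A [LabeledImageSet-class].
#' @param spec A [splitSpec()].
#' @return List with elements `train` and `validation`.
#' @export
splitImageSet <- function(set, spec = splitSpec()) {
  n <- length(set@images)
  if (!n) stop("cannot split an empty set")
  valIdx <- .withSeed(spec$seed, {
    if (spec$stratified) {
      unlist(lapply(split(seq_len(n), set@meta$class), function(idx) {
        sample(idx, round(length(idx) * spec$fraction))
      }), use.names = FALSE)
    } else {
      sample(seq_len(n), round(n * spec$fraction))
    }
  })
  valIdx <- sort(valIdx)
  trainIdx <- setdiff(seq_len(n), valIdx)
  list(train = set[trainIdx], validation = set[valIdx])
}
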