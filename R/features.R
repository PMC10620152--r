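#' Binary ingredient feature encoding with target masking
#'
#' Encodes each product as a binary bag-of-ingredients row over a fixed
#' vocabulary, with the column of the target ingredient removed ("masked") so
#' that its presence must be inferred, never read. With `decomposed = TRUE`
#' each product's ingredient set is first expanded through the compound
#' hierarchy. Tokens absent from `vocab` (e.g. ingredients seen only in
#' evaluation data) are ignored.
#'
#' @param catalog a `food_catalog`.
#' @param target normalized target ingredient token; must be in `vocab`.
#' @param decomposed expand compound ingredients into constituents first?
#' @param hmap a `hierarchy_map` (used only when `decomposed = TRUE`).
#' @param vocab encoding vocabulary; defaults to the catalog's ingredient
#'   vocabulary. Pass the training vocabulary when encoding evaluation data.
#' @return an object of class `feature_matrix`: list with `matrix` (sparse
#'   binary `dgCMatrix`, products x (|vocab| - 1)), `target`, `row_index`
#'   (product ids) and `vocab` (column tokens).
#' @export
encode_features <- function(catalog, target, decomposed = FALSE,
                            hmap = hierarchy_map(),
                            vocab = catalog$ingredient_vocab) {
  stopifnot(inherits(catalog, "food_catalog"))
  if (!target %in% vocab) {
    stop_foodgraph("unknown-target",
                   sprintf("target '%s' is not in the vocabulary", target))
  }
  cols <- setdiff(vocab, target)
  col_index <- stats::setNames(seq_along(cols), cols)
  ing <- catalog$products$ingredients
  if (decomposed) ing <- lapply(ing, decompose_ingredients, hmap = hmap)
  ij <- lapply(seq_along(ing), function(i) {
    j <- col_index[intersect(ing[[i]], cols)]
    if (length(j) == 0L) return(NULL)
    cbind(i = i, j = unname(j))
  })
  ij <- do.call(rbind, ij)
  m <- Matrix::sparseMatrix(
    i = if (is.null(ij)) integer(0) else ij[, "i"],
    j = if (is.null(ij)) integer(0) else ij[, "j"],
    x = 1,
    dims = c(length(ing), length(cols)),
    dimnames = list(catalog$products$product_id, cols)
  )
  structure(
    list(matrix = m, target = target,
         row_index = catalog$products$product_id, vocab = cols),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d products x %d ingredient columns (target '%s' masked)\n",
              nrow(x$matrix), ncol(x$matrix), x$target))
  invisible(x)
}
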