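#' Construct a product catalog
#'
#' A `food_catalog` holds one row per consumer food product (brand, category
#' set, price range, normalized ingredient tokens) together with sorted
#' ingredient and brand vocabularies. Ingredient strings are canonicalized via
#' [normalize_token()]; duplicate tokens within a product are collapsed.
#'
#' @param products a data frame with columns `product_id`, `name`, `brand`,
#'   `categories` (list of character), `price_min`, `price_max`,
#'   `ingredients` (list of character). Ingredients are assumed normalized;
#'   use [load_catalog()] for raw data.
#' @return an object of class `food_catalog`: a list with elements `products`
#'   (tibble), `ingredient_vocab` and `brand_vocab` (sorted character vectors).
#' @export
new_catalog <- function(products) {
  products <- tibble::as_tibble(products)
  required <- c("product_id", "name", "brand", "categories",
                "price_min", "price_max", "ingredients")
  missing <- setdiff(required, names(products))
  if (length(missing) > 0L) {
    stop("catalog is missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(products) == 0L) {
    stop_foodgraph("empty-catalog", "catalog has no products")
  }
  if (anyDuplicated(products$product_id)) {
    stop("product_id values must be unique")
  }
  if (any(products$price_min > products$price_max)) {
    stop("price_min must not exceed price_max")
  }
  if (any(lengths(products$ingredients) == 0L) ||
      any(lengths(products$categories) == 0L)) {
    stop("every product needs at least one ingredient and one category")
  }
  products$ingredients <- lapply(products$ingredients, function(x) unique(as.character(x)))
  products$categories <- lapply(products$categories, function(x) unique(as.character(x)))
  structure(
    list(
      products = products,
      ingredient_vocab = sort(unique(unlist(products$ingredients))),
      brand_vocab = sort(unique(products$brand))
    ),
    class = "food_catalog"
  )
}

#' @export
print.food_catalog <- function(x, ...) {
  cat(sprintf(
    "<food_catalog> %d products, %d brands, %d ingredient tokens, %d categories\n",
    nrow(x$products), length(x$brand_vocab), length(x$ingredient_vocab),
    length(unique(unlist(x$products$categories)))
  ))
  invisible(x)
}

#' @export
#' @rdname new_catalog
#' @param x a `food_catalog`.
n_products <- function(x) nrow(x$products)

#' Load and sanitize a product catalog
#'
#' Reads raw product records, drops records with missing/invalid required
#' fields (NaN prices, empty brand or ingredient list, `price_min` >
#' `price_max`), collapses exact duplicates (full-record equality after
#' normalization), normalizes every ingredient string and lowercases
#' categories. A load report (counts dropped per reason) is attached as the
#' `"load_report"` attribute and satisfies
#' `n_input == n_surviving + n_dropped_missing + n_dropped_duplicate`.
#'
#' @param source path to a file, or a data frame / list of records.
#' @param format `"csv"` or `"json"`. CSV columns are
#'   `id,name,brand,categories,price_min,price_max,ingredients`, with
#'   `categories` and `ingredients` `|`-separated within the cell. JSON is an
#'   array of objects with the same keys and list-valued categories/ingredients.
#' @param cfg a [normalization_config()].
#' @return a `food_catalog`; errors with class `"empty-catalog"` if no record
#'   survives.
#' @export
load_catalog <- function(source, format = c("csv", "json"),
                         cfg = normalization_config()) {
  format <- match.arg(format)
  recs <- read_records(source, format)
  n_input <- nrow(recs)
  if (n_input == 0L) stop_foodgraph("empty-catalog", "no records in source")

  # required-field screen (missing/NaN drop)
  ing_norm <- lapply(recs$ingredients, function(x) {
    x <- x[!is.na(x) & nzchar(trimws(x))]
    toks <- normalize_token(x, cfg, on_empty = "drop")
    unique(toks[!is.na(toks)])
  })
  cat_norm <- lapply(recs$categories, function(x) {
    x <- tolower(trimws(x[!is.na(x)]))
    unique(x[nzchar(x)])
  })
  brand <- trimws(as.character(recs$brand))
  name <- trimws(as.character(recs$name))
  ok <- !is.na(recs$price_min) & !is.na(recs$price_max) &
    is.finite(recs$price_min) & is.finite(recs$price_max) &
    recs$price_min >= 0 & recs$price_min <= recs$price_max &
    !is.na(brand) & nzchar(brand) & !is.na(name) & nzchar(name) &
    lengths(ing_norm) > 0L & lengths(cat_norm) > 0L
  n_missing <- sum(!ok)

  keep <- which(ok)
  key <- vapply(keep, function(i) {
    paste(name[i], brand[i],
          paste(sort(cat_norm[[i]]), collapse = "|"),
          recs$price_min[i], recs$price_max[i],
          paste(ing_norm[[i]], collapse = "|"),
          sep = "\r")
  }, character(1))
  dup <- duplicated(key)
  n_dup <- sum(dup)
  keep <- keep[!dup]

  if (length(keep) == 0L) {
    stop_foodgraph("empty-catalog", "no records survive sanitization")
  }
  ids <- as.character(recs$id[keep])
  if (anyNA(ids) || any(!nzchar(ids)) || anyDuplicated(ids)) {
    ids <- sprintf("p%05d", seq_along(keep))
  }
  cat_out <- new_catalog(tibble::tibble(
    product_id = ids,
    name = name[keep],
    brand = brand[keep],
    categories = cat_norm[keep],
    price_min = as.numeric(recs$price_min[keep]),
    price_max = as.numeric(recs$price_max[keep]),
    ingredients = ing_norm[keep]
  ))
  attr(cat_out, "load_report") <- list(
    n_input = n_input,
    n_dropped_missing = n_missing,
    n_dropped_duplicate = n_dup,
    n_surviving = length(keep)
  )
  cat_out
}

read_records <- function(source, format) {
  if (is.data.frame(source)) {
    df <- source
  } else if (is.character(source) && length(source) == 1L) {
    if (!file.exists(source)) stop("cannot read source: ", source)
    df <- if (format == "csv") {
      utils::read.csv(source, colClasses = "character", check.names = FALSE)
    } else {
      jsonlite::fromJSON(source, simplifyDataFrame = TRUE)
    }
  } else if (is.list(source)) {
    df <- jsonlite::fromJSON(jsonlite::toJSON(source, auto_unbox = TRUE),
                             simplifyDataFrame = TRUE)
  } else {
    stop("unsupported source type")
  }
  df <- tibble::as_tibble(df)
  if (nrow(df) == 0L) stop_foodgraph("empty-catalog", "no records in source")
  for (col in c("id", "name", "brand", "categories", "price_min",
                "price_max", "ingredients")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  split_cell <- function(x) {
    if (is.list(x)) return(lapply(x, as.character))
    lapply(strsplit(as.character(x), "|", fixed = TRUE), trimws)
  }
  df$categories <- split_cell(df$categories)
  df$ingredients <- split_cell(df$ingredients)
  df$price_min <- suppressWarnings(as.numeric(df$price_min))
  df$price_max <- suppressWarnings(as.numeric(df$price_max))
  df
}

#' Write a catalog to disk
#'
#' Inverse of [load_catalog()]: `load_catalog(write_catalog(c))` reproduces `c`
#' up to record order. Refuses to write an empty catalog.
#'
#' @param catalog a `food_catalog`.
#' @param dest output path.
#' @param format `"csv"` or `"json"`.
#' @export
write_catalog <- function(catalog, dest, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(catalog, "food_catalog"))
  if (nrow(catalog$products) == 0L) {
    stop_foodgraph("empty-catalog", "refusing to write an empty catalog")
  }
  p <- catalog$products
  if (format == "csv") {
    flat <- data.frame(
      id = p$product_id,
      name = p$name,
      brand = p$brand,
      categories = vapply(p$categories, paste, character(1), collapse = "|"),
      price_min = p$price_min,
      price_max = p$price_max,
      ingredients = vapply(p$ingredients, paste, character(1), collapse = "|"),
      stringsAsFactors = FALSE
    )
    utils::write.csv(flat, dest, row.names = FALSE)
  } else {
    recs <- lapply(seq_len(nrow(p)), function(i) {
      list(id = p$product_id[i], name = p$name[i], brand = p$brand[i],
           categories = p$categories[[i]], price_min = p$price_min[i],
           price_max = p$price_max[i], ingredients = p$ingredients[[i]])
    })
    jsonlite::write_json(recs, dest, auto_unbox = TRUE, digits = NA)
  }
  invisible(dest)
}
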