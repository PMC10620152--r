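#' Hierarchical (compound) ingredient maps
#'
#' Many listed ingredients are themselves composite foods: "peanut butter" on a
#' label usually implies peanuts, palm oil and salt even when those are not
#' listed. A `hierarchy_map` records, for each compound ingredient token, the
#' set of constituent tokens it implies. The token-to-constituent graph is
#' required to be acyclic.
#'
#' @param entries named list mapping compound token to a character vector of
#'   constituent tokens.
#' @return an object of class `hierarchy_map`.
#' @export
hierarchy_map <- function(entries = list()) {
  if (length(entries) > 0L) {
    stopifnot(!is.null(names(entries)), all(nzchar(names(entries))))
    entries <- lapply(entries, as.character)
    for (tok in names(entries)) {
      entries[[tok]] <- setdiff(unique(entries[[tok]]), tok)
    }
    if (hierarchy_is_cyclic(entries)) {
      stop_foodgraph("cyclic-hierarchy", "hierarchy entries form a cycle")
    }
  }
  structure(list(entries = entries), class = "hierarchy_map")
}

#' @export
print.hierarchy_map <- function(x, ...) {
  cat(sprintf("<hierarchy_map> %d compound ingredients\n", length(x$entries)))
  invisible(x)
}

hierarchy_is_cyclic <- function(entries) {
  color <- new.env(parent = emptyenv())  # 1 = in progress, 2 = done
  visit <- function(tok) {
    state <- color[[tok]]
    if (!is.null(state)) return(state == 1L)
    color[[tok]] <- 1L
    for (child in entries[[tok]]) {
      if (!is.null(entries[[child]]) && visit(child)) return(TRUE)
    }
    color[[tok]] <- 2L
    FALSE
  }
  for (tok in names(entries)) if (visit(tok)) return(TRUE)
  FALSE
}

#' Detect compound ingredients by cross-referencing products
#'
#' An ingredient token is treated as compound when it equals some product's
#' normalized name after that product's brand words are removed (e.g. a
#' product named "Brand Name Peanut Butter" makes "peanut butter" a compound
#' ingredient). Its constituents are the ingredients present in at least a
#' fraction `theta` of the matching products. Entries are inserted in
#' decreasing order of support (number of matching products); an entry that
#' would create a cycle is skipped. A product listing its own name as an
#' ingredient is ignored.
#'
#' @param catalog a `food_catalog` (ingredients already normalized).
#' @param theta constituent prevalence threshold across matching products
#'   (default 0.75).
#' @param cfg normalization config used on product names.
#' @return a `hierarchy_map` (possibly empty).
#' @export
build_hierarchy <- function(catalog, theta = 0.75,
                            cfg = normalization_config()) {
  stopifnot(inherits(catalog, "food_catalog"), theta > 0, theta <= 1)
  p <- catalog$products
  stripped <- vapply(seq_len(nrow(p)), function(i) {
    nm <- normalize_token(p$name[i], cfg, on_empty = "drop")
    if (is.na(nm)) return(NA_character_)
    brand_words <- strsplit(normalize_token(p$brand[i], cfg, on_empty = "drop"),
                            " ", fixed = TRUE)[[1]]
    words <- strsplit(nm, " ", fixed = TRUE)[[1]]
    words <- words[!words %in% brand_words]
    if (length(words) == 0L) NA_character_ else paste(words, collapse = " ")
  }, character(1))

  vocab <- catalog$ingredient_vocab
  candidates <- intersect(unique(stripped[!is.na(stripped)]), vocab)
  if (length(candidates) == 0L) return(hierarchy_map())

  proposals <- lapply(candidates, function(tok) {
    idx <- which(stripped == tok)
    tabs <- table(unlist(lapply(p$ingredients[idx], unique)))
    cons <- names(tabs)[tabs >= theta * length(idx)]
    cons <- setdiff(cons, tok)  # self-reference ignored
    list(token = tok, constituents = cons, support = length(idx))
  })
  proposals <- Filter(function(pr) length(pr$constituents) > 0L, proposals)
  proposals <- proposals[order(vapply(proposals, `[[`, integer(1), "support"),
                               decreasing = TRUE)]

  entries <- list()
  for (pr in proposals) {
    trial <- entries
    trial[[pr$token]] <- pr$constituents
    if (hierarchy_is_cyclic(trial)) {
      message("hierarchy: skipping cyclic entry for '", pr$token, "'")
    } else {
      entries <- trial
    }
  }
  hierarchy_map(entries)
}

#' Decompose an ingredient set through the compound hierarchy
#'
#' Returns the union of the input tokens with all constituents implied by the
#' hierarchy, applied recursively to a fixed point. Compound tokens are kept in
#' the result. The operation is monotone (input is a subset of the output) and
#' idempotent.
#'
#' @param ingredients character vector of normalized tokens.
#' @param hmap a `hierarchy_map`.
#' @return character vector: the decomposed ingredient set.
#' @export
decompose_ingredients <- function(ingredients, hmap = hierarchy_map()) {
  stopifnot(inherits(hmap, "hierarchy_map"))
  out <- unique(as.character(ingredients))
  frontier <- out
  while (length(frontier) > 0L) {
    new_toks <- unique(unlist(hmap$entries[intersect(frontier, names(hmap$entries))]))
    frontier <- setdiff(new_toks, out)
    out <- c(out, frontier)
  }
  out
}

#' Does a product (transitively) contain a target ingredient?
#'
#' Decomposition is used only to decide the label: the feature representation
#' of the product is never mutated. Equivalent to
#' `target %in% decompose_ingredients(ingredients, hmap)`.
#'
#' @inheritParams decompose_ingredients
#' @param target normalized target ingredient token.
#' @return logical scalar.
#' @export
contains_target <- function(ingredients, hmap = hierarchy_map(), target) {
  stopifnot(length(target) == 1L, nzchar(target))
  ingredients <- as.character(ingredients)
  if (target %in% ingredients) return(TRUE)
  seen <- ingredients
  frontier <- intersect(ingredients, names(hmap$entries))
  while (length(frontier) > 0L) {
    new_toks <- setdiff(unique(unlist(hmap$entries[frontier])), seen)
    if (target %in% new_toks) return(TRUE)
    seen <- c(seen, new_toks)
    frontier <- intersect(new_toks, names(hmap$entries))
  }
  FALSE
}

#' Read/write a hierarchy map as JSON
#'
#' Serialized as an object `{compound: [constituents, ...]}` so curated maps
#' can be edited by hand and reloaded.
#'
#' @param hmap a `hierarchy_map`.
#' @param path file path.
#' @export
write_hierarchy <- function(hmap, path) {
  stopifnot(inherits(hmap, "hierarchy_map"))
  jsonlite::write_json(hmap$entries, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_hierarchy
#' @export
read_hierarchy <- function(path) {
  hierarchy_map(jsonlite::fromJSON(path, simplifyVector = TRUE))
}
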