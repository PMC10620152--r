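#' Synthetic catalog simulation parameters
#'
#' The simulator emulates the statistical structure the graph methods assume:
#' brand-correlated ingredient usage (brands reuse a "house" ingredient set),
#' category-correlated composition and pricing (products of a category share
#' common ingredients and a price level), planted compound ingredients that
#' appear both as products and as ingredients of other products (with their
#' constituents omitted — hidden dependencies), target-ingredient presence
#' driven by brand effects and co-occurring correlate ingredients, and surface
#' alias forms that text normalization must collapse.
#'
#' @param n_products total products (including compound-ingredient products).
#' @param n_brands,n_ingredients,n_categories vocabulary sizes.
#' @param brand_signal strength `beta >= 0` of brand-specific ingredient
#'   propensities and of the brand effect on target presence; 0 removes all
#'   brand signal.
#' @param target_token primary target ingredient.
#' @param targets all planted target ingredients (the protocol's five by
#'   default); `target_token` must be among them.
#' @param target_base_rate marginal target presence rate aimed for by
#'   intercept calibration.
#' @param hierarchy_count number of planted compound ingredients (each also
#'   emitted as two products of different brands).
#' @param alias_rate probability an ingredient mention is emitted as a surface
#'   variant (plural/title case) rather than its canonical token.
#' @param price_range range of category base prices.
#' @param seed integer seed; catalogs are byte-identical given the same seed.
#' @param n_correlates correlate ingredients per target.
#' @param correlate_weight log-odds added to target presence per correlate
#'   ingredient present.
#' @param mean_ingredients mean ingredient-list length.
#' @param compound_rate probability a product lists a compound ingredient.
#' @param price_sigma lognormal sd of product price around its category base.
#' @return object of class `sim_params` (the desk-scale preset by default).
#' @export
sim_params <- function(n_products = 1500L, n_brands = 40L,
                       n_ingredients = 300L, n_categories = 20L,
                       brand_signal = 2, target_token = "palm oil",
                       targets = c("palm oil", "wheat", "milk", "egg", "soya"),
                       target_base_rate = 0.3, hierarchy_count = 10L,
                       alias_rate = 0.1, price_range = c(1, 20), seed = 1L,
                       n_correlates = 20L, correlate_weight = 2.8,
                       mean_ingredients = 10, compound_rate = 0.3,
                       price_sigma = 0.18) {
  stopifnot(n_products > 0, n_brands > 1, n_ingredients > 0, n_categories > 0,
            brand_signal >= 0, target_base_rate >= 0, target_base_rate <= 1,
            alias_rate >= 0, alias_rate <= 1, hierarchy_count >= 0,
            target_token %in% targets)
  if (hierarchy_count + length(targets) + n_correlates >= n_ingredients) {
    stop("n_ingredients too small for the requested targets, correlates and compounds")
  }
  if (2L * hierarchy_count > n_products) {
    stop("hierarchy_count too large for n_products")
  }
  structure(as.list(environment()), class = "sim_params")
}

# pronounceable, normalization-stable synthetic words
make_words <- function(n, syllables = 3L) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  out <- character(0)
  while (length(out) < n) {
    batch <- vapply(seq_len(2L * (n - length(out))), function(i) {
      paste0(sample(cons, syllables, TRUE), sample(vow, syllables, TRUE),
             collapse = "")
    }, character(1))
    batch <- vapply(batch, stem_fixpoint, character(1), USE.NAMES = FALSE)
    out <- unique(c(out, batch))
  }
  out[seq_len(n)]
}

alias_of <- function(token) {
  words <- strsplit(token, " ", fixed = TRUE)[[1]]
  last <- words[length(words)]
  can_plural <- grepl("[a-rt-xz]$", last)
  pick <- sample(if (can_plural) 1:3 else 2:3, 1L)
  if (pick == 1L) {
    words[length(words)] <- paste0(last, "s")
    paste(words, collapse = " ")
  } else if (pick == 2L) {
    paste(vapply(words, function(w) {
      paste0(toupper(substr(w, 1, 1)), substr(w, 2, nchar(w)))
    }, character(1)), collapse = " ")
  } else {
    toupper(token)
  }
}

#' Generate a synthetic product catalog with known ground truth
#'
#' See [sim_params()] for the generative model. The raw records (with alias
#' surface forms) are passed through the same sanitization path as
#' [load_catalog()], so the returned catalog is normalized.
#'
#' @param params a [sim_params()].
#' @return list with `catalog` (a `food_catalog`) and `truth` (class
#'   `sim_truth`): per-product target presence for every planted target, the
#'   planted `hierarchy_map`, brand effects and correlate sets.
#' @export
generate_catalog <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(params$seed, generate_catalog_impl(params))
}

generate_catalog_impl <- function(params) {
  n_fill <- params$n_ingredients - length(params$targets) - params$hierarchy_count
  pool <- make_words(n_fill + params$hierarchy_count + 2L * params$n_brands +
                       params$n_categories + 60L)
  filler <- pool[seq_len(n_fill)]
  pool <- pool[-seq_len(n_fill)]
  compound_tokens <- if (params$hierarchy_count > 0) {
    paste(pool[seq_len(params$hierarchy_count)], "blend")
  } else character(0)
  pool <- pool[-seq_len(max(params$hierarchy_count, 1L))]
  brand_names <- vapply(seq_len(params$n_brands), function(b) {
    w <- pool[c(2L * b - 1L, 2L * b)]
    paste(vapply(w, function(x) paste0(toupper(substr(x, 1, 1)),
                                       substr(x, 2, nchar(x))), character(1)),
          collapse = " ")
  }, character(1))
  pool <- pool[-seq_len(2L * params$n_brands)]
  categories <- pool[seq_len(params$n_categories)]
  name_words <- pool[-seq_len(params$n_categories)]

  beta <- params$brand_signal
  brand_effect <- stats::setNames(stats::rnorm(params$n_brands), brand_names)
  brand_house <- lapply(seq_len(params$n_brands), function(b) {
    sample(filler, ceiling(0.15 * n_fill))
  })
  cat_house <- lapply(seq_len(params$n_categories), function(cidx) {
    sample(filler, ceiling(0.2 * n_fill))
  })
  cat_price <- stats::runif(params$n_categories, params$price_range[1],
                            params$price_range[2])
  correlates <- stats::setNames(
    lapply(params$targets, function(t) sample(filler, params$n_correlates)),
    params$targets)
  # each target concentrates in "prone" categories where its correlates are
  # common (the palm-oil-in-confectionery pattern); elsewhere they are rare
  prone_cats <- stats::setNames(
    lapply(params$targets, function(t) {
      sample.int(params$n_categories, max(1L, round(0.3 * params$n_categories)))
    }), params$targets)
  pop <- stats::setNames(stats::rgamma(n_fill, 0.8) + 0.05, filler)
  pop[unique(unlist(correlates))] <- pop[unique(unlist(correlates))] * 0.25

  # category-conditional ingredient weights (house set + target correlates)
  cat_weights <- function(cat_idx) {
    w <- pop
    w[cat_house[[cat_idx]]] <- w[cat_house[[cat_idx]]] * 4
    for (t in params$targets) {
      if (cat_idx %in% prone_cats[[t]]) {
        w[correlates[[t]]] <- w[correlates[[t]]] * 40
      }
    }
    w
  }

  # each compound is a composite food of a home category: its constituents
  # follow that category's composition, and it may itself contain targets
  compound_home <- sample.int(params$n_categories, params$hierarchy_count,
                              replace = TRUE)
  constituents <- lapply(seq_len(params$hierarchy_count), function(k) {
    cons <- sample(filler, sample(4:6, 1L), prob = cat_weights(compound_home[k]))
    p_target <- ifelse(vapply(params$targets, function(t) {
      compound_home[k] %in% prone_cats[[t]]
    }, logical(1)), 0.5, 0.05)
    unique(c(cons, params$targets[stats::runif(length(params$targets)) < p_target]))
  })
  names(constituents) <- compound_tokens

  n_comp_products <- 2L * params$hierarchy_count
  n_regular <- params$n_products - n_comp_products
  ids <- sprintf("s%05d", seq_len(params$n_products))

  recs <- vector("list", params$n_products)
  truth_rows <- vector("list", params$n_products)
  brand_weights <- stats::rgamma(params$n_brands, 2)

  title_case <- function(tok) paste(vapply(
    strsplit(tok, " ")[[1]],
    function(w) paste0(toupper(substr(w, 1, 1)), substr(w, 2, nchar(w))),
    character(1)), collapse = " ")

  make_price <- function(cat_idx) {
    mid <- cat_price[cat_idx] * exp(stats::rnorm(1, 0, params$price_sigma))
    u <- stats::runif(1, 0.02, 0.10)
    c(min = mid * (1 - u), max = mid * (1 + u))
  }

  row <- 0L
  for (k in seq_len(params$hierarchy_count)) {
    bpair <- sample.int(params$n_brands, 2L)
    for (b in bpair) {
      row <- row + 1L
      cat_idx <- compound_home[k]
      pr <- make_price(cat_idx)
      ing <- unique(c(constituents[[k]], sample(filler, 1L)))
      recs[[row]] <- list(
        id = ids[row],
        name = paste(brand_names[b], title_case(compound_tokens[k])),
        brand = brand_names[b], categories = categories[cat_idx],
        price_min = pr["min"], price_max = pr["max"], ingredients = ing)
      truth_rows[[row]] <- params$targets %in% constituents[[k]]
    }
  }

  # regular products: brand/category-weighted ingredient draws
  reg_brand <- sample.int(params$n_brands, n_regular, TRUE, prob = brand_weights)
  reg_cat1 <- sample.int(params$n_categories, n_regular, TRUE)
  for (i in seq_len(n_regular)) {
    row <- row + 1L
    b <- reg_brand[i]
    cat_idx <- reg_cat1[i]
    n_extra_cat <- stats::rbinom(1, 2, 0.2)
    cats <- unique(c(cat_idx, sample.int(params$n_categories, n_extra_cat)))
    k_ing <- 3L + stats::rpois(1, max(params$mean_ingredients - 3, 0))
    k_ing <- min(k_ing, n_fill)
    w <- cat_weights(cat_idx)
    w[brand_house[[b]]] <- w[brand_house[[b]]] * (1 + beta)
    ing <- sample(filler, k_ing, prob = w)
    if (params$hierarchy_count > 0 && stats::runif(1) < params$compound_rate) {
      # composite ingredients tend to come from the product's own category
      home_match <- compound_tokens[compound_home == cat_idx]
      comp <- if (length(home_match) > 0 && stats::runif(1) < 0.7) {
        sample(home_match, 1L)
      } else {
        sample(compound_tokens, 1L)
      }
      ing <- c(setdiff(ing, constituents[[comp]]), comp)
    }
    recs[[row]] <- list(
      id = ids[row], name = paste(brand_names[b], paste(
        title_case(sample(name_words, 1L)), title_case(sample(name_words, 1L)))),
      brand = brand_names[b], categories = categories[cats],
      price_min = NA_real_, price_max = NA_real_, ingredients = ing)
    pr <- make_price(cat_idx)
    recs[[row]]$price_min <- pr["min"]
    recs[[row]]$price_max <- pr["max"]
    truth_rows[[row]] <- rep(FALSE, length(params$targets))
  }

  # target presence for regular products: brand effect + correlate co-occurrence
  reg_rows <- n_comp_products + seq_len(n_regular)
  decomposed_of <- function(r) {
    ing <- recs[[r]]$ingredients
    unique(c(ing, unlist(constituents[intersect(ing, compound_tokens)])))
  }
  for (ti in seq_along(params$targets)) {
    t <- params$targets[ti]
    corr <- correlates[[t]]
    s <- 0.4 * beta * brand_effect[reg_brand] + params$correlate_weight *
      vapply(reg_rows, function(r) sum(decomposed_of(r) %in% corr), numeric(1))
    alpha <- if (params$target_base_rate == 0) {
      -Inf
    } else if (params$target_base_rate == 1) {
      Inf
    } else {
      stats::uniroot(function(a) mean(stats::plogis(a + s)) - params$target_base_rate,
                     c(-40, 40))$root
    }
    y <- stats::runif(n_regular) < stats::plogis(alpha + s)
    for (i in seq_len(n_regular)) {
      r <- reg_rows[i]
      implied <- any(vapply(intersect(recs[[r]]$ingredients, compound_tokens),
                            function(cp) t %in% constituents[[cp]], logical(1)))
      if (y[i]) {
        # hidden dependency: an implied target is sometimes left off the label
        if (!implied || stats::runif(1) < 0.5) {
          recs[[r]]$ingredients <- c(recs[[r]]$ingredients, t)
        }
      }
      truth_rows[[r]][ti] <- y[i] || implied
    }
  }

  # emit raw records with alias surface forms
  raw <- tibble::tibble(
    id = vapply(recs, `[[`, character(1), "id"),
    name = vapply(recs, `[[`, character(1), "name"),
    brand = vapply(recs, `[[`, character(1), "brand"),
    categories = lapply(recs, `[[`, "categories"),
    price_min = vapply(recs, function(r) unname(r$price_min), numeric(1)),
    price_max = vapply(recs, function(r) unname(r$price_max), numeric(1)),
    ingredients = lapply(recs, function(r) {
      vapply(r$ingredients, function(tok) {
        if (stats::runif(1) < params$alias_rate) alias_of(tok) else tok
      }, character(1), USE.NAMES = FALSE)
    })
  )
  catalog <- load_catalog(raw, format = "json")
  presence <- do.call(rbind, truth_rows)
  colnames(presence) <- params$targets
  keep <- match(catalog$products$product_id, ids)
  truth <- structure(
    list(target_presence = tibble::tibble(
           product_id = catalog$products$product_id,
           tibble::as_tibble(presence[keep, , drop = FALSE])),
         hierarchy = hierarchy_map(constituents),
         brand_effects = brand_effect,
         correlates = correlates),
    class = "sim_truth")
  list(catalog = catalog, truth = truth)
}

#' Generate a catalog plus its ground-truth substitution edge set
#'
#' Categories and prices are arranged (fewer categories, tighter within-
#' category price spread) so that a material share of ordered pairs satisfies
#' all four substitution criteria. The edge set is computed with
#' [enumerate_substitutions()] against the planted hierarchy and is guaranteed
#' non-empty; if a draw yields no edges the seed is advanced a bounded number
#' of times before erroring.
#'
#' @param params a [sim_params()]; fixture presets override `n_categories`
#'   and `price_sigma` unless `tighten = FALSE`.
#' @param criteria a [criteria_config()].
#' @param tighten apply the fixture price/category tightening.
#' @param max_retries seed advances allowed before giving up.
#' @return list with `catalog`, `graph` (a `substitution_graph`) and `truth`.
#' @export
generate_substitution_fixture <- function(params = sim_params(n_products = 1000L),
                                          criteria = criteria_config(),
                                          tighten = TRUE, max_retries = 5L) {
  stopifnot(inherits(params, "sim_params"))
  if (tighten) {
    params$n_categories <- min(params$n_categories, 6L)
    params$price_sigma <- min(params$price_sigma, 0.08)
  }
  for (attempt in 0:max_retries) {
    p <- params
    p$seed <- params$seed + attempt
    gen <- generate_catalog(p)
    graph <- enumerate_substitutions(gen$catalog, params$target_token,
                                     gen$truth$hierarchy, criteria)
    if (nrow(graph$pos_edges) > 0L) {
      return(list(catalog = gen$catalog, graph = graph, truth = gen$truth))
    }
  }
  stop_foodgraph("empty-substitution-fixture",
                 "no criteria-valid substitution edges after bounded retries")
}
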