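#' Crowder configuration
#'
#' A set of inert molecular crowders, each pinned at a 1-based duplex site
#' with a dimensionless strength \code{alpha} that multiplies the Morse
#' depth of that site (\code{D = alpha * D0}); \code{alpha > 1} stabilises
#' the pair, \code{alpha = 1} is a no-op. A site may carry several
#' crowders; how they combine is set by \code{multiplicity_rule}:
#' \code{"product"} (default) multiplies the alphas at the site,
#' \code{"single"} collapses duplicates to one alpha (the first listed).
#'
#' @param sites integer vector of 1-based site indices.
#' @param alpha crowder strengths, recycled to \code{length(sites)}; all
#'   must be > 0.
#' @param multiplicity_rule \code{"product"} or \code{"single"}.
#' @return An object of class \code{crowder_config}.
#' @examples
#' crowder_config(c(2, 7, 8), alpha = 1.5)
#' crowder_config(c(4, 4, 8), alpha = 1.5)  # doubly crowded site 4
#' @export
crowder_config <- function(sites = integer(0), alpha = 1.5,
                           multiplicity_rule = c("product", "single")) {
  multiplicity_rule <- match.arg(multiplicity_rule)
  sites <- as.integer(sites)
  if (length(sites) > 0) {
    alpha <- rep_len(as.numeric(alpha), length(sites))
    if (any(!is.finite(alpha)) || any(alpha <= 0)) {
      stop("all alpha values must be finite and > 0", call. = FALSE)
    }
    if (any(sites < 1L)) stop("crowder sites must be >= 1", call. = FALSE)
  } else {
    alpha <- numeric(0)
  }
  structure(list(sites = sites, alpha = alpha,
                 multiplicity_rule = multiplicity_rule),
            class = "crowder_config")
}

#' @export
print.crowder_config <- function(x, ...) {
  if (length(x$sites) == 0) {
    cat("crowder config: none (uncrowded duplex)\n")
  } else {
    cat(sprintf("crowder config (%d crowders, %s rule): %s\n",
                length(x$sites), x$multiplicity_rule,
                paste(sprintf("%d:%g", x$sites, x$alpha), collapse = ", ")))
  }
  invisible(x)
}

#' Enumerate all placements of k identical crowders on an N-site duplex
#'
#' With \code{allow_repeats = FALSE} this is the set of k-element site
#' subsets (crowders are identical, so placements are unordered):
#' \code{choose(N, k)} configurations — 56 for three crowders on an 8-bp
#' duplex. With \code{allow_repeats = TRUE} it is the set of k-multisets
#' (a site may hold several crowders), \code{choose(N + k - 1, k)}
#' configurations. The list is deterministic, lexicographically ordered by
#' the sorted site tuple.
#'
#' @param n duplex length.
#' @param k number of crowders.
#' @param alpha strength assigned to every crowder.
#' @param allow_repeats allow several crowders on one site?
#' @param multiplicity_rule passed to [crowder_config()]; only matters when
#'   repeats occur.
#' @return A list of \code{crowder_config} objects.
#' @examples
#' length(enumerate_crowder_configs(8, 3))                        # 56
#' length(enumerate_crowder_configs(8, 3, allow_repeats = TRUE))  # 120
#' @export
enumerate_crowder_configs <- function(n, k, alpha = 1.5,
                                      allow_repeats = FALSE,
                                      multiplicity_rule = "product") {
  n <- as.integer(n); k <- as.integer(k)
  if (n < 1L || k < 1L) stop("need n >= 1 and k >= 1", call. = FALSE)
  if (!allow_repeats && k > n) {
    stop("k > n impossible without repeats (", k, " crowders, ", n,
         " sites)", call. = FALSE)
  }
  site_sets <- if (allow_repeats) {
    # k-multisets of {1..n} via the standard stars-and-bars bijection with
    # k-subsets of {1..n+k-1}
    m <- utils::combn(n + k - 1L, k)
    m - (seq_len(k) - 1L)
  } else {
    utils::combn(n, k)
  }
  lapply(seq_len(ncol(site_sets)), function(j) {
    crowder_config(site_sets[, j], alpha = alpha,
                   multiplicity_rule = multiplicity_rule)
  })
}

# Effective per-site alpha vector of length n (1 where uncrowded).
effective_alpha <- function(crowders, n) {
  a <- rep(1, n)
  if (is.null(crowders) || length(crowders$sites) == 0) return(a)
  if (any(crowders$sites > n)) {
    stop("crowder site ", max(crowders$sites), " exceeds duplex length ", n,
         call. = FALSE)
  }
  if (crowders$multiplicity_rule == "product") {
    for (i in seq_along(crowders$sites)) {
      s <- crowders$sites[i]
      a[s] <- a[s] * crowders$alpha[i]
    }
  } else {
    keep <- !duplicated(crowders$sites)
    a[crowders$sites[keep]] <- crowders$alpha[keep]
  }
  a
}

#' Per-site Morse depths under a crowder configuration
#'
#' Site i gets depth \code{alpha_eff(i) * D0(class_i)} where \code{D0} is
#' the class depth (\code{D_AT} or \code{D_GC}) and \code{alpha_eff} is 1
#' at uncrowded sites. An AT site under a single alpha = 1.5 crowder, for
#' example, deepens from 0.0395 to 0.05925 eV.
#'
#' @param duplex a \code{pbd_duplex}.
#' @param crowders a \code{crowder_config} or \code{NULL} (uncrowded).
#' @param params a [pbd_params()] object.
#' @return Numeric vector of depths (eV), length \code{duplex$n}.
#' @export
effective_depths <- function(duplex, crowders = NULL, params = pbd_params()) {
  base_depths(duplex, params) * effective_alpha(crowders, duplex$n)
}

#' Read a crowder configuration from YAML or JSON
#'
#' Expected layout: a top-level \code{crowders} list of \code{{site,
#' alpha}} mappings, e.g. \code{crowders: [{site: 2, alpha: 1.5}, ...]};
#' an optional top-level \code{multiplicity_rule}.
#'
#' @param path a \code{.yaml}/\code{.yml}/\code{.json} file.
#' @return A \code{crowder_config}.
#' @export
read_crowder_config <- function(path) {
  cfg <- read_config_file(path)
  if (is.null(cfg$crowders)) {
    stop("config ", path, " has no top-level 'crowders' list", call. = FALSE)
  }
  entries <- cfg$crowders
  # jsonlite may simplify to a data.frame; yaml gives a list of maps
  if (is.data.frame(entries)) {
    sites <- entries$site; alpha <- entries$alpha
  } else {
    sites <- vapply(entries, function(e) as.numeric(e$site), numeric(1))
    alpha <- vapply(entries, function(e) as.numeric(e$alpha), numeric(1))
  }
  if (anyNA(sites) || anyNA(alpha)) {
    stop("every crowder entry needs 'site' and 'alpha'", call. = FALSE)
  }
  rule <- cfg$multiplicity_rule %||% "product"
  crowder_config(sites, alpha, multiplicity_rule = rule)
}

#' Parse the compact crowder syntax \code{"site:alpha[,site:alpha...]"}
#'
#' CLI helper; repeated sites are allowed and combined according to
#' \code{multiplicity_rule}.
#'
#' @param text e.g. \code{"2:1.5,7:1.5,8:1.5"}; empty string gives an
#'   uncrowded config.
#' @param multiplicity_rule passed through.
#' @return A \code{crowder_config}.
#' @export
parse_crowder_spec <- function(text, multiplicity_rule = "product") {
  if (is.null(text) || !nzchar(text)) {
    return(crowder_config(multiplicity_rule = multiplicity_rule))
  }
  parts <- strsplit(strsplit(text, ",")[[1]], ":")
  bad <- vapply(parts, function(p) length(p) != 2L || anyNA(suppressWarnings(as.numeric(p))), logical(1))
  if (any(bad)) {
    stop("malformed crowder spec element '",
         paste(parts[[which(bad)[1]]], collapse = ":"),
         "'; expected site:alpha", call. = FALSE)
  }
  crowder_config(vapply(parts, function(p) as.numeric(p[1]), numeric(1)),
                 vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
                 multiplicity_rule = multiplicity_rule)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
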