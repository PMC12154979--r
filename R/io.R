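#' Write a melting profile to CSV (with JSON summary)
#'
#' The CSV has columns \code{T_K, f_eV, Cv_kB, phi} and a comment header
#' embedding the duplex, crowder configuration, full parameter set and a
#' config hash, so a run can be reproduced from its own output. A sidecar
#' \code{<path>.json} carries Tm and the same metadata machine-readably.
#'
#' @param profile a \code{melting_profile} from [melting_scan()].
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_profile <- function(profile, path) {
  meta <- profile_metadata(profile)
  hdr <- c(
    sprintf("# pbdmelt melting profile"),
    sprintf("# duplex: %s (%s)", profile$duplex$label,
            format_duplex(profile$duplex)),
    sprintf("# crowders: %s", meta$crowders),
    sprintf("# params: %s", meta$params_line),
    sprintf("# config_hash: %s", meta$hash),
    sprintf("# Tm_K: %.6f", profile$tm)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("T_K,f_eV,Cv_kB,phi", con)
  df <- profile$profile
  writeLines(sprintf("%.10g,%.10g,%.10g,%.10g", df$temperature,
                     df$free_energy, df$cv, df$phi), con)
  jsonlite::write_json(
    list(tm_K = profile$tm, duplex = format_duplex(profile$duplex),
         label = profile$duplex$label, crowders = meta$crowders,
         params = unclass(profile$params), config_hash = meta$hash,
         settings = profile$settings),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

profile_metadata <- function(profile) {
  cr <- if (is.null(profile$crowders) || length(profile$crowders$sites) == 0) {
    "none"
  } else {
    paste(sprintf("%d:%g", profile$crowders$sites, profile$crowders$alpha),
          collapse = ",")
  }
  pl <- paste(names(profile$params),
              vapply(profile$params, function(v) format(v, digits = 12),
                     character(1)),
              sep = "=", collapse = " ")
  list(crowders = cr, params_line = pl,
       hash = config_hash(list(format_duplex(profile$duplex), cr,
                               unclass(profile$params), profile$settings)))
}

# Deterministic short hash of any serialisable config (no external deps:
# fold the serialisation bytes through a 32-bit FNV-1a). Arithmetic is done
# in doubles with an explicit split multiply because the running value
# exceeds R's integer range.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  p <- 16777619
  h <- 2166136261
  for (b in bytes) {
    # xor touches the low byte only (b < 256)
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    # (h * p) mod 2^32 without losing double precision
    h0 <- h %% 65536
    h1 <- h %/% 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

#' Read back a profile CSV written by [write_profile()]
#'
#' @param path CSV path.
#' @return Data frame with columns \code{temperature, free_energy, cv,
#'   phi}; attributes \code{tm} and \code{header} carry the metadata.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  names(df) <- c("temperature", "free_energy", "cv", "phi")
  tm_line <- grep("^# Tm_K:", hdr, value = TRUE)
  attr(df, "tm") <- if (length(tm_line)) {
    as.numeric(sub("^# Tm_K: *", "", tm_line[1]))
  } else {
    NA_real_
  }
  attr(df, "header") <- hdr
  df
}

#' Read an experimental melting curve
#'
#' Two-column CSV with header \code{T,phi}; temperatures in kelvin or
#' degrees Celsius (converted as T_K = T_C + 273.15). Used only for
#' overlaying/scoring against model curves — no experimental data ships
#' with the package.
#'
#' @param path CSV path.
#' @param unit \code{"K"} or \code{"C"}.
#' @return Data frame with columns \code{temperature} (K) and \code{phi}.
#' @export
read_experimental_curve <- function(path, unit = c("K", "C")) {
  unit <- match.arg(unit)
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop("malformed CSV ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (!all(c("T", "phi") %in% names(df))) {
    stop("experimental curve needs header columns 'T' and 'phi'",
         call. = FALSE)
  }
  bad <- which(!is.finite(df$T) | !is.finite(df$phi) |
                 df$phi < 0 | df$phi > 1)
  if (length(bad) > 0) {
    stop("invalid experimental row at line ", bad[1] + 1,
         " (phi must be in [0,1], T finite)", call. = FALSE)
  }
  temperature <- if (unit == "C") df$T + 273.15 else df$T
  data.frame(temperature = temperature, phi = df$phi)
}

#' RMS difference between a model profile and an experimental curve
#'
#' Interpolates the model \eqn{\phi(T)} linearly onto the experimental
#' temperatures (restricted to the model scan range) and reports the
#' root-mean-square difference.
#'
#' @param profile a \code{melting_profile} (scanned with \code{phi = TRUE}).
#' @param experimental data frame from [read_experimental_curve()].
#' @return RMS difference (dimensionless, same scale as phi).
#' @export
overlay_rms <- function(profile, experimental) {
  df <- profile$profile
  if (all(is.na(df$phi))) stop("profile has no phi column; rerun with phi = TRUE",
                               call. = FALSE)
  keep <- experimental$temperature >= min(df$temperature) &
    experimental$temperature <= max(df$temperature)
  if (!any(keep)) stop("experimental curve does not overlap the scan range",
                       call. = FALSE)
  mod <- stats::approx(df$temperature, df$phi,
                       xout = experimental$temperature[keep])$y
  sqrt(mean((mod - experimental$phi[keep])^2))
}

#' Write an opening map as long-format CSV
#'
#' Columns \code{site, T_K, P_open}, one row per (site, temperature).
#'
#' @param map an \code{opening_map}.
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_opening_map <- function(map, path) {
  df <- data.frame(site = rep(map$sites, times = length(map$temperatures)),
                   T_K = rep(map$temperatures, each = length(map$sites)),
                   P_open = as.vector(map$P))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Plot a melting curve
#'
#' \eqn{\phi(T)} with the Cv-peak Tm marked; an experimental curve can be
#' overlaid. Requires ggplot2.
#'
#' @param profile a \code{melting_profile}.
#' @param experimental optional data frame from
#'   [read_experimental_curve()].
#' @return A ggplot object.
#' @export
plot_melting <- function(profile, experimental = NULL) {
  require_ggplot()
  df <- profile$profile
  g <- ggplot2::ggplot(df, ggplot2::aes(x = temperature,
                                        y = phi)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_vline(xintercept = profile$tm, linetype = "dashed") +
    ggplot2::labs(x = "Temperature (K)", y = "Fraction open ϕ",
                  title = sprintf("%s — Tm = %.2f K", profile$duplex$label,
                                  profile$tm))
  if (!is.null(experimental)) {
    g <- g + ggplot2::geom_point(data = experimental,
                                 ggplot2::aes(x = temperature,
                                              y = phi),
                                 colour = "steelblue", size = 1)
  }
  g
}

#' Plot an opening map as a heat map
#'
#' Site x temperature map of opening probabilities; crowded sites show as
#' dark (closed) streaks persisting to high temperature.
#'
#' @param map an \code{opening_map}.
#' @return A ggplot object.
#' @export
plot_opening_map <- function(map) {
  require_ggplot()
  df <- data.frame(site = rep(map$sites, times = length(map$temperatures)),
                   temperature = rep(map$temperatures,
                                     each = length(map$sites)),
                   P = as.vector(map$P))
  ggplot2::ggplot(df, ggplot2::aes(x = temperature, y = site,
                                   fill = P)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), name = "P(open)") +
    ggplot2::labs(x = "Temperature (K)", y = "Base-pair site")
}

require_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
}
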