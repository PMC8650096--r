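## Design space: factor table, full-factorial enumeration, design naming codec.

#' Construct a factor table for the device design space
#'
#' A factor table holds the levels of the eight design factors swept in a
#' full-factorial design screen: the two supply flow rates, the left/right
#' infusion-connector widths and heights, the microwell chamber radius, and
#' the spheroid porosity. Level lists must be non-empty, strictly increasing
#' and positive; porosities must lie strictly inside (0, 1).
#'
#' The left connector admits the sentinel level `0.1` um for its width and
#' height: a 0.1 um duct is far below any continuum channel scale and encodes
#' a *closed* left connector, i.e. the single-supply-channel (SSC) topology.
#'
#' @param q1,q2 flow-rate levels for the left and right supply channel (ml/h).
#' @param wl,wr connector width levels, left and right (um).
#' @param hl,hr connector height levels, left and right (um).
#' @param radius chamber radius levels (um).
#' @param phi spheroid porosity levels (dimensionless, in (0, 1)).
#' @return An object of class `factor_table` (a named list of numeric levels).
#' @seealso [default_factor_table()] for the reference levels,
#'   [enumerate_designs()] for the Cartesian product.
#' @export
factor_table <- function(q1, q2, wl, wr, hl, hr, radius, phi) {
  tab <- list(q1 = q1, q2 = q2, wl = wl, wr = wr, hl = hl, hr = hr,
              radius = radius, phi = phi)
  for (f in names(tab)) {
    lv <- tab[[f]]
    if (!is.numeric(lv) || length(lv) == 0L)
      stop("invalid factor table: factor '", f, "' has an empty level list")
    if (anyNA(lv) || any(lv <= 0))
      stop("invalid factor table: factor '", f, "' has non-positive levels")
    if (is.unsorted(lv, strictly = TRUE))
      stop("invalid factor table: levels of '", f,
           "' must be strictly increasing")
  }
  if (any(phi >= 1))
    stop("invalid factor table: porosity levels must lie strictly in (0, 1)")
  structure(tab, class = "factor_table")
}

#' Factor levels of the reference design screen
#'
#' Eight factors with 2 x 2 x 5 x 4 x 5 x 4 x 3 x 4 = 19,200 combinations:
#' flow rates 0.01/0.02 ml/h per channel, connector widths and heights
#' 20-60 um (left side additionally the closed sentinel 0.1 um), chamber
#' radii 80/120/160 um and spheroid porosities 0.2-0.9.
#'
#' @return A `factor_table`.
#' @export
default_factor_table <- function() {
  factor_table(q1 = c(0.01, 0.02), q2 = c(0.01, 0.02),
               wl = c(0.1, 20, 30, 40, 60), wr = c(20, 30, 40, 60),
               hl = c(0.1, 20, 30, 40, 60), hr = c(20, 30, 40, 60),
               radius = c(80, 120, 160), phi = c(0.2, 0.5, 0.7, 0.9))
}

#' Read a factor table from a YAML file
#'
#' The file holds one key per factor (`q1`, `q2`, `wl`, `wr`, `hl`, `hr`,
#' `radius`, `phi`), each a list of levels. The packaged default file
#' `system.file("extdata", "factors_table.yaml", package = "spherochip")`
#' ships the reference design-screen levels.
#'
#' @param path path to a YAML file.
#' @return A `factor_table`.
#' @export
read_factor_table <- function(path) {
  raw <- yaml::read_yaml(path)
  need <- c("q1", "q2", "wl", "wr", "hl", "hr", "radius", "phi")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("factor file is missing factors: ", paste(miss, collapse = ", "))
  do.call(factor_table, lapply(raw[need], as.numeric))
}

#' @export
print.factor_table <- function(x, ...) {
  cat("Device design factor table\n")
  for (f in names(x))
    cat(sprintf("  %-7s %d level(s): %s\n", f, length(x[[f]]),
                paste(x[[f]], collapse = ", ")))
  cat(sprintf("  full-factorial designs: %d\n",
              prod(vapply(x, length, 1L))))
  invisible(x)
}

#' Enumerate the full-factorial design space
#'
#' Forms the Cartesian product of all factor levels, ordered lexicographically
#' by (phi, radius, wr, hr, wl, hl, q1, q2) with the last field varying
#' fastest. The ordering is deterministic, so repeated calls (and sweep
#' schedules built on them) are reproducible.
#'
#' @param table a [factor_table()].
#' @return A data frame of class `design_table` with one row per design and
#'   columns `name`, `phi`, `radius_um`, `wl_um`, `wr_um`, `hl_um`, `hr_um`,
#'   `q1_ml_h`, `q2_ml_h`, `topology` (`"SSC"` when the left connector is at
#'   the closed sentinel, `"DSC"` otherwise).
#' @export
enumerate_designs <- function(table) {
  if (!inherits(table, "factor_table"))
    table <- do.call(factor_table, as.list(table))
  ## expand.grid varies the first column fastest; feed factors reversed so
  ## that q2 is fastest and phi slowest
  g <- expand.grid(q2 = table$q2, q1 = table$q1, hl = table$hl, wl = table$wl,
                   hr = table$hr, wr = table$wr, radius = table$radius,
                   phi = table$phi, KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(
    name = design_name(g$phi, g$wr, g$radius, g$hr, g$wl, g$hl),
    phi = g$phi, radius_um = g$radius,
    wl_um = g$wl, wr_um = g$wr, hl_um = g$hl, hr_um = g$hr,
    q1_ml_h = g$q1, q2_ml_h = g$q2,
    topology = ifelse(is_closed_level(g$wl) | is_closed_level(g$hl),
                      "SSC", "DSC"),
    stringsAsFactors = FALSE)
  class(out) <- c("design_table", "data.frame")
  out
}

#' @export
print.design_table <- function(x, ...) {
  cat(sprintf("Design table: %d designs (%d SSC, %d DSC)\n",
              nrow(x), sum(x$topology == "SSC"), sum(x$topology == "DSC")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

## closed-connector sentinel (um)
CLOSED_LEVEL <- 0.1

is_closed_level <- function(x) abs(x - CLOSED_LEVEL) < 1e-9

#' Construct a single design point
#'
#' @param phi spheroid porosity in (0, 1).
#' @param radius chamber radius (um).
#' @param wl,wr,hl,hr connector widths/heights (um); `0.1` um on the left side
#'   marks a closed connector (SSC topology).
#' @param q1,q2 supply flow rates (ml/h); `q1` is ignored for SSC designs.
#' @return A one-row `design_table`.
#' @export
design_point <- function(phi, radius, wr, hr, wl, hl, q1 = 0.01, q2 = 0.01) {
  stopifnot(phi > 0, phi < 1, radius > 0, wr > 0, hr > 0, wl > 0, hl > 0,
            q1 >= 0, q2 >= 0)
  ## off-grid levels (e.g. 25 um connectors) get a lenient decimal name
  name <- tryCatch(design_name(phi, wr, radius, hr, wl, hl),
                   error = function(e) design_name_lenient(phi, wr, radius,
                                                           hr, wl, hl))
  d <- data.frame(name = name,
                  phi = phi, radius_um = radius, wl_um = wl, wr_um = wr,
                  hl_um = hl, hr_um = hr, q1_ml_h = q1, q2_ml_h = q2,
                  topology = if (is_closed_level(wl) || is_closed_level(hl))
                    "SSC" else "DSC",
                  stringsAsFactors = FALSE)
  class(d) <- c("design_table", "data.frame")
  d
}

encode_length_digit <- function(x, what) {
  out <- character(length(x))
  closed <- is_closed_level(x)
  out[closed] <- "0"
  rest <- x[!closed]
  if (length(rest)) {
    tens <- rest / 10
    if (any(abs(tens - round(tens)) > 1e-9) || any(tens < 1))
      stop("cannot encode ", what, " level ", rest[which.max(
        abs(tens - round(tens)))], " um: not a positive multiple of 10 um")
    out[!closed] <- as.character(round(tens))
  }
  out
}

#' Encode a design as its canonical name
#'
#' Designs are named `P<p>.Wr<w>.R<r>.Hr<h>.Wl<w>.Hl<h>`: porosity as its
#' first decimal digit (`P9` is 0.9), lengths in tens of um (`Wr6` is 60 um,
#' `R12` is 120 um), and the closed-connector sentinel (0.1 um) as digit 0.
#' Flow rates are not part of the name; a name plus a flow scenario keys one
#' simulation record.
#'
#' @param phi porosity; must be a multiple of 0.1 in (0, 1).
#' @param wr,radius,hr,wl,hl lengths (um); multiples of 10 um, or 0.1 um for
#'   a closed left connector.
#' @return Character vector of design names.
#' @export
design_name <- function(phi, wr, radius, hr, wl, hl) {
  p10 <- phi * 10
  if (any(abs(p10 - round(p10)) > 1e-9) || any(round(p10) < 1) ||
      any(round(p10) > 9))
    stop("cannot encode porosity ", phi[which.max(abs(p10 - round(p10)))],
         ": not a one-digit multiple of 0.1 in (0, 1)")
  paste0("P", round(p10),
         ".Wr", encode_length_digit(wr, "connector width (right)"),
         ".R",  encode_length_digit(radius, "chamber radius"),
         ".Hr", encode_length_digit(hr, "connector height (right)"),
         ".Wl", encode_length_digit(wl, "connector width (left)"),
         ".Hl", encode_length_digit(hl, "connector height (left)"))
}

## same naming scheme but with decimal tens-of-um fields, for levels outside
## the canonical single-digit grid (e.g. 25 um -> "2.5")
design_name_lenient <- function(phi, wr, radius, hr, wl, hl) {
  num <- function(x) ifelse(is_closed_level(x), "0",
                            as.character(signif(x / 10, 6)))
  paste0("P", as.character(signif(phi * 10, 6)), ".Wr", num(wr),
         ".R", num(radius), ".Hr", num(hr), ".Wl", num(wl),
         ".Hl", num(hl))
}

#' Decode a design name into geometry and porosity
#'
#' Inverse of [design_name()] on its image. Flow rates are supplied
#' separately (they are not encoded in the name).
#'
#' @param name a design name such as `"P9.Wr6.R8.Hr6.Wl6.Hl2"`.
#' @param q1,q2 flow rates (ml/h) to attach to the decoded design.
#' @return A one-row `design_table`.
#' @export
decode_design_name <- function(name, q1 = 0.01, q2 = 0.01) {
  stopifnot(is.character(name), length(name) == 1L)
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  tags <- c("P", "Wr", "R", "Hr", "Wl", "Hl")
  if (length(parts) != 6L)
    stop("malformed design name '", name, "': expected 6 dot-separated ",
         "segments ", paste0(tags, "<digits>", collapse = "."))
  vals <- numeric(6)
  for (i in seq_along(tags)) {
    m <- regmatches(parts[i], regexec(paste0("^", tags[i], "([0-9]+)$"),
                                      parts[i]))[[1]]
    if (length(m) != 2L)
      stop("malformed design name '", name, "': segment '", parts[i],
           "' does not match ", tags[i], "<digits>")
    vals[i] <- as.numeric(m[2])
  }
  phi <- vals[1] / 10
  if (phi <= 0 || phi >= 1)
    stop("malformed design name '", name, "': porosity digit must be 1-9")
  len <- function(v) if (v == 0) CLOSED_LEVEL else v * 10
  design_point(phi = phi, wr = len(vals[2]), radius = len(vals[3]),
               hr = len(vals[4]), wl = len(vals[5]), hl = len(vals[6]),
               q1 = q1, q2 = q2)
}

#' Write a design manifest CSV
#'
#' One row per design with columns `name`, `phi`, `radius_um`, `wl_um`,
#' `wr_um`, `hl_um`, `hr_um`, `q1_ml_h`, `q2_ml_h`, `topology`.
#'
#' @param designs a `design_table` from [enumerate_designs()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_design_manifest <- function(designs, path) {
  utils::write.csv(as.data.frame(designs), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
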