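#' Component registry
#'
#' A registry maps raw two-character component abbreviations, as used in
#' 13-digit brand codes, onto canonical symbol identities. Registration
#' systems often carry redundant abbreviations for rotated versions of the
#' same glyph (e.g. a backslash and a forward slash); the registry collapses
#' these to one canonical symbol and records the rotation offset (in degrees)
#' that the redundant abbreviation implies.
#'
#' @param abbrev character vector of raw 2-character abbreviations (unique).
#' @param symbol character vector of canonical symbol ids, same length;
#'   several abbreviations may map to the same symbol.
#' @param offset_degrees numeric rotation offset in `[0, 360)` added when an
#'   abbreviation is canonicalised (default 0 for all).
#' @return An object of class `component_registry`: a data frame with columns
#'   `abbrev`, `symbol`, `offset_degrees`, plus a `symbols` attribute listing
#'   the canonical alphabet in a stable order.
#' @export
component_registry <- function(abbrev, symbol, offset_degrees = 0) {
  abbrev <- as.character(abbrev)
  symbol <- as.character(symbol)
  if (length(abbrev) != length(symbol))
    stop("abbrev and symbol must have the same length")
  if (anyDuplicated(abbrev))
    stop("each raw abbreviation must map to exactly one canonical symbol")
  if (any(nchar(abbrev) != 2L))
    stop("abbreviations must be exactly 2 characters")
  offset_degrees <- rep_len(as.numeric(offset_degrees), length(abbrev))
  if (any(offset_degrees < 0 | offset_degrees >= 360))
    stop("rotation offsets must lie in [0, 360)")
  reg <- data.frame(abbrev = abbrev, symbol = symbol,
                    offset_degrees = offset_degrees,
                    stringsAsFactors = FALSE)
  attr(reg, "symbols") <- unique(symbol)
  class(reg) <- c("component_registry", "data.frame")
  reg
}

#' Synthetic component registry
#'
#' Builds a registry with `n_symbols` canonical symbols (`S001`, `S002`, ...),
#' one abbreviation per symbol and zero rotation offsets. The default size of
#' 103 mirrors the size of the component alphabet in the Kansas brand books.
#'
#' @param n_symbols number of canonical symbols (<= 260).
#' @return A [component_registry].
#' @export
synthetic_registry <- function(n_symbols = 103) {
  stopifnot(n_symbols >= 1, n_symbols <= 260)
  ab <- as.vector(outer(LETTERS, 0:9, paste0))[seq_len(n_symbols)]
  component_registry(ab, sprintf("S%03d", seq_len(n_symbols)))
}

registry_symbols <- function(registry) attr(registry, "symbols")

#' Canonicalise one raw component code
#'
#' Converts a raw abbreviation plus rotation digit into a canonical component:
#' the registry's symbol id and a rotation in degrees. The rotation digit
#' encodes multiples of `rotation_step` degrees (45 by default, giving eight
#' orientations per digit); the registry's offset for the abbreviation is
#' added, so two redundant abbreviations of the same symbol yield rotations
#' differing by their offset difference.
#'
#' @param abbrev raw 2-character abbreviation.
#' @param rotation_digit integer 0-9 (or a 1-character digit string).
#' @param registry a [component_registry].
#' @param rotation_step degrees per rotation digit (default 45).
#' @return list with elements `symbol` (character) and `rotation` (degrees in
#'   `[0, 360)`).
#' @export
canonicalize <- function(abbrev, rotation_digit, registry, rotation_step = 45) {
  i <- match(abbrev, registry$abbrev)
  if (is.na(i))
    stop(sprintf("unknown component abbreviation '%s'", abbrev))
  digit <- as.integer(rotation_digit)
  if (is.na(digit) || digit < 0L || digit > 9L)
    stop(sprintf("invalid rotation digit '%s'", rotation_digit))
  list(symbol = registry$symbol[i],
       rotation = (digit * rotation_step + registry$offset_degrees[i]) %% 360)
}

#' Parse a 13-digit brand code
#'
#' A brand code has four 3-character component slots followed by one
#' body-location digit. Each occupied slot holds a 2-character abbreviation
#' and a rotation digit; unused trailing slots hold the filler token.
#'
#' @param code 13-character string.
#' @param registry a [component_registry].
#' @param filler 3-character token marking an unoccupied slot (default
#'   `"___"`).
#' @param rotation_step degrees per rotation digit.
#' @return A list of class `brand` with fields `symbols` (character vector,
#'   length 1-4), `rotations` (degrees), `location` (1-character string).
#' @export
parse_brand_code <- function(code, registry, filler = "___",
                             rotation_step = 45) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 13L)
    stop("brand code must be a single 13-character string")
  slots <- substring(code, c(1L, 4L, 7L, 10L), c(3L, 6L, 9L, 12L))
  occupied <- slots != filler
  if (!any(occupied))
    stop("malformed brand code: all four component slots are empty")
  symbols <- character(0); rotations <- numeric(0)
  for (k in which(occupied)) {
    ab <- substr(slots[k], 1L, 2L)
    dg <- substr(slots[k], 3L, 3L)
    cc <- tryCatch(canonicalize(ab, dg, registry, rotation_step),
                   error = function(e)
                     stop(sprintf("slot %d: %s", k, conditionMessage(e)),
                          call. = FALSE))
    symbols <- c(symbols, cc$symbol)
    rotations <- c(rotations, cc$rotation)
  }
  structure(list(symbols = symbols, rotations = rotations,
                 location = substr(code, 13L, 13L)),
            class = "brand")
}

#' Serialise a brand back to its 13-digit code
#'
#' Inverse of [parse_brand_code()] for brands expressible in the slot grammar.
#' Each symbol is written with the first registry abbreviation whose offset is
#' compatible with the brand's rotation (rotation minus offset must be a
#' multiple of `rotation_step`).
#'
#' @inheritParams parse_brand_code
#' @param brand a `brand` object.
#' @return 13-character string.
#' @export
serialize_brand_code <- function(brand, registry, filler = "___",
                                 rotation_step = 45) {
  n <- length(brand$symbols)
  stopifnot(n >= 1, n <= 4)
  slots <- rep(filler, 4L)
  for (k in seq_len(n)) {
    rows <- which(registry$symbol == brand$symbols[k])
    if (!length(rows))
      stop(sprintf("symbol '%s' not in registry", brand$symbols[k]))
    done <- FALSE
    for (i in rows) {
      d <- (brand$rotations[k] - registry$offset_degrees[i]) %% 360
      if (d %% rotation_step == 0 && d / rotation_step <= 9) {
        slots[k] <- paste0(registry$abbrev[i], d / rotation_step)
        done <- TRUE
        break
      }
    }
    if (!done)
      stop(sprintf("rotation %s of symbol '%s' not expressible",
                   brand$rotations[k], brand$symbols[k]))
  }
  paste0(paste(slots, collapse = ""), brand$location)
}

#' Spatial registry
#'
#' Resolves zip zones to counties and counties to one of four quadrants
#' (NW, NE, SW, SE). Zips are opaque labels; quadrant membership is pure
#' configuration (mirroring county-based rectangular regions), no geometry
#' is computed.
#'
#' @param zip,county character vectors (one row per zip).
#' @param quadrant character vector of quadrant labels per zip, each one of
#'   `"NW"`, `"NE"`, `"SW"`, `"SE"`.
#' @return Object of class `spatial_registry`.
#' @export
spatial_registry <- function(zip, county, quadrant) {
  zip <- as.character(zip); county <- as.character(county)
  quadrant <- as.character(quadrant)
  stopifnot(length(zip) == length(county), length(zip) == length(quadrant))
  if (anyDuplicated(zip)) stop("duplicate zip in spatial registry")
  bad <- setdiff(unique(quadrant), c("NW", "NE", "SW", "SE"))
  if (length(bad))
    stop("quadrants must be NW/NE/SW/SE; got: ", paste(bad, collapse = ", "))
  cq <- tapply(quadrant, county, function(q) unique(q))
  if (any(lengths(cq) > 1))
    stop("a county maps to more than one quadrant")
  structure(list(zip = zip, county = county, quadrant = quadrant),
            class = "spatial_registry")
}

#' Resolve zips through a spatial registry
#'
#' @param zips character vector of zip zones.
#' @param spatial a [spatial_registry].
#' @return data frame with columns `zip`, `county`, `quadrant`.
#' @export
resolve_zip <- function(zips, spatial) {
  i <- match(as.character(zips), spatial$zip)
  if (anyNA(i))
    stop("zip(s) not in spatial registry: ",
         paste(unique(zips[is.na(i)]), collapse = ", "))
  data.frame(zip = spatial$zip[i], county = spatial$county[i],
             quadrant = spatial$quadrant[i], stringsAsFactors = FALSE)
}

#' Brand population snapshot
#'
#' The central container: all brands active in a given year. Components are
#' stored as an `n x 4` integer matrix of indices into the canonical symbol
#' alphabet (0 marks an empty slot); rotations as a parallel numeric matrix
#' in degrees.
#'
#' @param components integer matrix `n x 4` (0 = empty slot); each row must
#'   have 1-4 leading non-zero entries.
#' @param zip character vector of zip zones (length n).
#' @param first_year,last_year integer vectors; `last_year` may be `NA`
#'   (still active).
#' @param year snapshot calendar year.
#' @param symbols character vector: the canonical symbol alphabet indexed by
#'   the entries of `components`.
#' @param spatial a [spatial_registry] resolving every zip, or `NULL`.
#' @param rotations numeric matrix like `components` (default all 0).
#' @param location character vector of body-location digits (default "1").
#' @return Object of class `brand_population`.
#' @export
brand_population <- function(components, zip, first_year,
                             last_year = NA_integer_, year, symbols,
                             spatial = NULL, rotations = NULL,
                             location = NULL) {
  components <- as.matrix(components)
  storage.mode(components) <- "integer"
  if (ncol(components) != 4L) stop("components must have 4 columns")
  n <- nrow(components)
  n_comp <- rowSums(components > 0L)
  if (n > 0 && (any(n_comp < 1L) || any(n_comp > 4L)))
    stop("every brand must have 1-4 components")
  if (any(components > length(symbols)))
    stop("component index exceeds symbol alphabet")
  zip <- rep_len(as.character(zip), n)
  first_year <- rep_len(as.integer(first_year), n)
  last_year <- rep_len(as.integer(last_year), n)
  if (any(!is.na(last_year) & first_year > last_year))
    stop("first_year must be <= last_year")
  if (n > 0 && any(first_year > year | (!is.na(last_year) & last_year < year)))
    stop("all brands must be active in the snapshot year")
  if (!is.null(spatial)) resolve_zip(unique(zip), spatial)
  if (is.null(rotations)) rotations <- matrix(0, n, 4L)
  if (is.null(location)) location <- rep("1", n)
  structure(list(components = components, rotations = rotations,
                 n_comp = as.integer(n_comp), zip = zip,
                 first_year = first_year, last_year = last_year,
                 location = rep_len(as.character(location), n),
                 year = as.integer(year), symbols = as.character(symbols),
                 spatial = spatial),
            class = "brand_population")
}

#' @export
print.brand_population <- function(x, ...) {
  cat(sprintf("brand_population: %d brands, year %d, %d-symbol alphabet\n",
              nrow(x$components), x$year, length(x$symbols)))
  invisible(x)
}

#' Number of brands in a population
#' @param pop a [brand_population].
#' @return integer count.
#' @export
n_brands <- function(pop) nrow(pop$components)

subset_population <- function(pop, idx) {
  brand_population(pop$components[idx, , drop = FALSE], pop$zip[idx],
                   pop$first_year[idx], pop$last_year[idx], pop$year,
                   pop$symbols, pop$spatial,
                   pop$rotations[idx, , drop = FALSE], pop$location[idx])
}

population_codes <- function(pop, registry, filler = "___",
                             rotation_step = 45) {
  vapply(seq_len(n_brands(pop)), function(i) {
    k <- pop$n_comp[i]
    b <- structure(list(symbols = pop$symbols[pop$components[i, seq_len(k)]],
                        rotations = pop$rotations[i, seq_len(k)],
                        location = pop$location[i]), class = "brand")
    serialize_brand_code(b, registry, filler, rotation_step)
  }, character(1))
}

#' Remove duplicate brand codes within zip zones
#'
#' Registries accumulate duplicate codes when one ranch registers the same
#' design several times (typically for different body locations); such
#' duplicates are removed when they share a zip zone. Identical codes in
#' different zips usually denote genuinely different arrangements of the same
#' components and are all kept. Within a zip, the retained instance is the
#' one with the earliest first year (ties: input order).
#'
#' @param brands data frame with columns `code13` and `zip` (and optionally
#'   `first_year`).
#' @return The deduplicated data frame (original row order preserved).
#' @export
deduplicate <- function(brands) {
  stopifnot(is.data.frame(brands), all(c("code13", "zip") %in% names(brands)))
  if (nrow(brands) == 0L) return(brands)
  fy <- if ("first_year" %in% names(brands)) brands$first_year
        else rep(0L, nrow(brands))
  key <- paste(brands$code13, brands$zip, sep = "\r")
  ord <- order(key, fy, seq_len(nrow(brands)))
  keep_sorted <- !duplicated(key[ord])
  keep <- sort(ord[keep_sorted])
  brands[keep, , drop = FALSE]
}

#' Read / write brand populations
#'
#' File schema (CSV): header `code13,zip,book_year`, optionally followed by
#' `first_year,last_year`. JSON: an array of objects with the same keys.
#' Every row must parse under the registry and resolve under the spatial
#' registry; violations are reported with their row number.
#'
#' @param path file path.
#' @param format `"csv"` or `"json"`.
#' @param registry a [component_registry].
#' @param spatial a [spatial_registry].
#' @param filler,rotation_step slot-grammar configuration, see
#'   [parse_brand_code()].
#' @return [read_population()] returns a [brand_population];
#'   [write_population()] returns `path` invisibly.
#' @export
read_population <- function(path, format = c("csv", "json"), registry,
                            spatial, filler = "___", rotation_step = 45) {
  format <- match.arg(format)
  df <- if (format == "csv") {
    utils::read.csv(path, colClasses = "character")
  } else {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  }
  need <- c("code13", "zip", "book_year")
  if (!all(need %in% names(df)))
    stop("population file must have columns: ", paste(need, collapse = ", "))
  year <- unique(as.integer(df$book_year))
  if (length(year) != 1L)
    stop("a population file must hold a single book_year snapshot")
  symbols <- registry_symbols(registry)
  n <- nrow(df)
  comp <- matrix(0L, n, 4L); rot <- matrix(0, n, 4L)
  for (i in seq_len(n)) {
    b <- tryCatch(parse_brand_code(df$code13[i], registry, filler,
                                   rotation_step),
                  error = function(e)
                    stop(sprintf("row %d: %s", i, conditionMessage(e)),
                         call. = FALSE))
    k <- length(b$symbols)
    comp[i, seq_len(k)] <- match(b$symbols, symbols)
    rot[i, seq_len(k)] <- b$rotations
  }
  loc <- substr(df$code13, 13L, 13L)
  fy <- if ("first_year" %in% names(df)) as.integer(df$first_year)
        else rep(year, n)
  ly <- if ("last_year" %in% names(df)) as.integer(df$last_year)
        else rep(NA_integer_, n)
  miss <- setdiff(unique(df$zip), spatial$zip)
  if (length(miss))
    stop("zip(s) not resolvable in spatial registry: ",
         paste(miss, collapse = ", "))
  brand_population(comp, df$zip, fy, ly, year, symbols, spatial, rot, loc)
}

#' @rdname read_population
#' @param pop a [brand_population].
#' @export
write_population <- function(pop, path, format = c("csv", "json"), registry,
                             filler = "___", rotation_step = 45) {
  format <- match.arg(format)
  df <- data.frame(code13 = population_codes(pop, registry, filler,
                                             rotation_step),
                   zip = pop$zip, book_year = pop$year,
                   first_year = pop$first_year, last_year = pop$last_year,
                   stringsAsFactors = FALSE)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", na = "null")
  }
  invisible(path)
}

#' Read / write registries
#'
#' Registry CSV schema: `abbrev,symbol,offset_degrees`. Spatial CSV schema:
#' `zip,county,quadrant`.
#'
#' @param path file path.
#' @return the corresponding object.
#' @export
read_registry <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  component_registry(df$abbrev, df$symbol, as.numeric(df$offset_degrees))
}

#' @rdname read_registry
#' @param registry a [component_registry].
#' @export
write_registry <- function(registry, path) {
  utils::write.csv(as.data.frame(registry), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname read_registry
#' @export
read_spatial <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  spatial_registry(df$zip, df$county, df$quadrant)
}

#' @rdname read_registry
#' @param spatial a [spatial_registry].
#' @export
write_spatial <- function(spatial, path) {
  utils::write.csv(data.frame(zip = spatial$zip, county = spatial$county,
                              quadrant = spatial$quadrant),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
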