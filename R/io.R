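fmt17 <- function(x) sprintf("%.17g", x)

#' Write / read a gridded field as long-format CSV
#'
#' Long format (cell, species, sector, value) with 17 significant digits,
#' so a write-read round trip reproduces doubles bit-exactly.
#'
#' @param field array [cell, species, sector] or an
#'   \linkS4class{EmissionField}
#' @param path CSV path
#' @return (read) an array [cell, species, sector]
#' @export
writeFieldCSV <- function(field, path) {
  if (is(field, "EmissionField")) field <- field@values
  dn <- dimnames(field)
  df <- data.frame(
    cell = rep(seq_len(dim(field)[1]), times = prod(dim(field)[2:3])),
    species = rep(rep(dn[[2]], each = dim(field)[1]), times = dim(field)[3]),
    sector = rep(dn[[3]], each = prod(dim(field)[1:2])),
    value = fmt17(as.vector(field)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFieldCSV
#' @export
readFieldCSV <- function(path) {
  hdr <- gsub('"', "", strsplit(readLines(path, n = 1L), ",")[[1]])
  for (col in c("cell", "species", "sector", "value"))
    if (!col %in% hdr)
      stop("format error: missing column '", col, "' in ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(cell = "integer", species = "character",
                                       sector = "character", value = "character"))
  sp <- unique(df$species); sec <- unique(df$sector)
  n <- max(df$cell)
  arr <- array(NA_real_, dim = c(n, length(sp), length(sec)),
               dimnames = list(NULL, sp, sec))
  arr[cbind(df$cell, match(df$species, sp), match(df$sector, sec))] <-
    as.numeric(df$value)
  arr
}

#' Write / read a country mask as CSV
#'
#' @param mask a \linkS4class{RegionMask}
#' @param path CSV path
#' @export
writeMaskCSV <- function(mask, path) {
  utils::write.csv(
    data.frame(cell = seq_along(mask@assignment), country = mask@assignment),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeMaskCSV
#' @export
readMaskCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cell", "country") %in% names(df)))
    stop("format error: mask CSV needs columns 'cell' and 'country'")
  assign <- df$country[order(df$cell)]
  assign[assign %in% c("", "NA")] <- NA_character_
  new("RegionMask", assignment = assign,
      countries = sort(unique(assign[!is.na(assign)])))
}

#' Serialize a contribution tensor to long CSV
#'
#' Columns receptor, source, sector, species, pollutant, value (17
#' significant digits).
#'
#' @param tensor a \linkS4class{ContributionTensor}
#' @param path CSV path
#' @export
writeContributionsCSV <- function(tensor, path) {
  v <- tensor@values
  dn <- dimnames(v)
  grid <- expand.grid(receptor = dn[[1]], source = dn[[2]], sector = dn[[3]],
                      species = dn[[4]], stringsAsFactors = FALSE)
  grid$pollutant <- tensor@pollutant
  grid$value <- fmt17(as.vector(v))
  utils::write.csv(grid, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeContributionsCSV
#' @export
readContributionsCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = list(value = "character"))
  need <- c("receptor", "source", "sector", "species", "pollutant", "value")
  for (col in need)
    if (!col %in% names(df)) stop("format error: missing column '", col, "'")
  rec <- unique(df$receptor); src <- unique(df$source)
  sec <- unique(df$sector); sp <- unique(df$species)
  v <- array(NA_real_, dim = c(length(rec), length(src), length(sec), length(sp)),
             dimnames = list(rec, src, sec, sp))
  v[cbind(match(df$receptor, rec), match(df$source, src),
          match(df$sector, sec), match(df$species, sp))] <- as.numeric(df$value)
  new("ContributionTensor", values = v, pollutant = df$pollutant[1],
      unassigned = array(0, dim = c(length(rec), length(sec), length(sp)),
                         dimnames = list(rec, sec, sp)))
}
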