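# A synthetic emulation of the CARICOMP monitoring network: real station
# metadata (ids, habitats, coordinates, record spans) for the 29
# long-term stations, with synthetic weekly measurements, synthetic
# short-record stations, and synthetic covariates generated to carry the
# statistical structure the analysis targets. Every measurement here is
# simulated; only the station descriptions are real.

#' Long-term CARICOMP station metadata
#'
#' Station descriptions (id, country, site, habitat, coordinates, record
#' span) for the 29 stations of the CARICOMP monitoring network with
#' long-term environmental records.
#'
#' @return data.frame with one row per station.
#' @export
caricomp_station_table <- function() {
  txt <- "station_id|country|site|habitat|latitude|longitude|first|last
BARr|Barbados|Bellairs|reef|13.192|-59.642|1992-11|1999-12
BARs|Barbados|Bellairs|seagrass|13.068|-59.578|1992-11|1996-09
BELr|Belize|Carrie Bow Cay|reef|16.800|-88.067|1993-01|2015-07
BELs|Belize|Carrie Bow Cay|seagrass|16.825|-88.099|1993-01|2015-07
BERr|Bermuda|Hog Breaker Reef|reef|32.344|-64.865|1992-09|2002-12
BERs|Bermuda|North Seagrass|seagrass|32.401|-64.799|1992-09|2002-12
BONr|Bonaire|Barcadera Reef|reef|12.195|-68.301|1994-08|1997-12
COLr|Colombia|Chengue Bay|reef|11.328|-74.128|1992-09|2011-06
COLm|Colombia|Chengue Bay|mangrove|11.317|-74.128|1992-09|2011-06
COLs|Colombia|Chengue Bay|seagrass|11.321|-74.127|1992-09|2011-06
CRIs|Costa Rica|Rio Perezoso|seagrass|9.737|-82.807|1999-03|2015-05
JAMr|Jamaica|Discovery Bay|reef|18.472|-77.414|1992-09|2002-02
JAMm|Jamaica|Discovery Bay|mangrove|18.469|-77.415|1992-09|2002-02
JAMs|Jamaica|Discovery Bay|seagrass|18.471|-77.414|1992-09|2002-02
MEXr|Mexico|Puerto Morelos|reef|20.878|-86.845|1992-10|2005-10
MEXs|Mexico|Puerto Morelos|seagrass|20.868|-86.867|1992-09|2005-10
PANr|Panama|STRI Colon|reef|9.349|-82.266|1999-06|2015-05
PANm|Panama|STRI Colon|mangrove|9.352|-82.259|1999-02|2015-05
PANs|Panama|STRI Colon|seagrass|9.352|-82.258|1999-06|2015-05
PURr|Puerto Rico|La Parguera|reef|17.935|-67.049|1993-01|2014-12
PURs|Puerto Rico|La Parguera|seagrass|17.955|-67.043|1993-01|2014-12
SABr|Saba|Ladder Labyrinth|reef|17.626|-63.260|1992-09|1997-04
USAs|USA|Long Key|seagrass|24.800|-80.717|1996-07|2004-06
VENr1|Venezuela|Morrocoy Caiman|reef|10.852|-68.232|1992-09|1999-11
VENr2|Venezuela|Morrocoy Cayo Sombrero|reef|10.881|-68.213|2000-02|2012-11
VENm|Venezuela|Morrocoy|mangrove|10.836|-68.261|1993-01|2012-11
VENs|Venezuela|Morrocoy|seagrass|10.858|-68.291|1992-09|2012-11
VEN2m|Venezuela|Punta de Mangle|mangrove|10.864|-64.058|1993-01|2003-12
VEN2s|Venezuela|Punta de Mangle|seagrass|10.864|-64.058|1993-01|2003-12"
  utils::read.table(text = txt, header = TRUE, sep = "|",
                    stringsAsFactors = FALSE)
}

# months between two "YYYY-MM" strings, inclusive of both end months
.span_months <- function(first, last) {
  f <- as.integer(strsplit(first, "-")[[1]])
  l <- as.integer(strsplit(last, "-")[[1]])
  as.integer((l[1] * 12 + l[2]) - (f[1] * 12 + f[2]) + 1L)
}

# trend magnitude that is a multiple of the smallest detectable trend at
# this record length, noise SD and autocorrelation
.plant_omega <- function(sigma_N, phi, n_years, margin = 3) {
  margin * 3.3 * sigma_N * sqrt((1 + phi) / (1 - phi)) / n_years^1.5
}

#' Simulate a CARICOMP-like environmental database
#'
#' Generates a fully synthetic weekly environmental database shaped like
#' the CARICOMP network: the 29 long-term stations of
#' [caricomp_station_table()] keep their real habitats, coordinates and
#' record spans, and 19 additional short-record stations (synthetic
#' codes) bring the network to its full 48 stations across 20 reef, 19
#' seagrass and 9 mangrove sites, of which only the long-term 29 survive
#' the record filter. Temperature is generated for all stations (except
#' one long-term seagrass station, so 28 long-term temperature series are
#' analysable), visibility only for reef and seagrass stations (24
#' long-term series): mangrove sites carry no Secchi record.
#'
#' Station trends are planted: five temperature series increase (one
#' mangrove, two seagrass, two reef) and one decreases, ten visibility
#' series decrease (six reef, four seagrass) and two increase, with
#' magnitudes three times the smallest detectable trend at the station's
#' record length so the planted categories are recoverable. All other
#' stations have zero trend. Synthetic covariates are drawn conditional
#' on the planted visibility category: visibility losses co-occur with
#' large population growth, low wave exposure, weak currents and wetting
#' rainfall; gains with the opposite.
#'
#' @param seed Integer seed.
#' @param gap_fraction Month-level missingness applied to every series.
#' @return List with `weekly` (wide observation data.frame), `metadata`
#'   (48 stations), `covariates` (per long-term station), and
#'   `true_categories` (list with `temperature` and `visibility` named
#'   character vectors).
#' @export
simulate_caricomp_like <- function(seed = 1, gap_fraction = 0.1) {
  set.seed(seed)
  long_md <- caricomp_station_table()
  n_long <- nrow(long_md)

  # synthetic short-record stations complete the 48-station network
  # (20 reefs, 19 seagrass, 9 mangroves in total)
  short_ids <- c("TATr", "CURr", "CUBr", "BAHr", "DREr", "COL2r", "USAr",
                 "CRIr",
                 "TATs", "CURs", "CUBs", "BAHs", "DREs", "BONs", "SABs",
                 "TATm", "CURm", "BELm", "MEXm")
  short_hab <- c(rep("reef", 8), rep("seagrass", 7), rep("mangrove", 4))
  short_md <- data.frame(
    station_id = short_ids, country = "synthetic", site = "synthetic",
    habitat = short_hab,
    latitude = round(stats::runif(length(short_ids), 9, 27), 3),
    longitude = round(stats::runif(length(short_ids), -88, -60), 3),
    first = "1995-01", last = "1996-12", stringsAsFactors = FALSE)
  # short records: 18-28 latent months, below both filter thresholds
  short_months <- sample(18:28, length(short_ids), replace = TRUE)

  metadata <- rbind(long_md, short_md)

  # planted trend categories
  temp_inc <- c("COLr", "PURr", "COLs", "PURs", "COLm")
  temp_dec <- "BONr"
  vis_dec <- c("COLr", "VENr1", "VENr2", "JAMr", "BARr", "SABr",
               "VENs", "VEN2s", "BARs", "CRIs")
  vis_inc <- c("JAMs", "BERr")
  no_temperature <- "USAs"   # one long-term station records Secchi only

  months <- vapply(seq_len(n_long), function(i)
    .span_months(long_md$first[i], long_md$last[i]), integer(1))
  yrs <- months / 12

  # per-station noise conditions (temperature): Puerto Morelos is the
  # quietest (shortest detection time), eastern Venezuela the noisiest
  sigmaT <- stats::runif(n_long, 0.5, 1.0)
  phiT <- stats::runif(n_long, 0.25, 0.55)
  names(sigmaT) <- names(phiT) <- long_md$station_id
  sigmaT[c("MEXr", "MEXs")] <- c(0.33, 0.36)
  phiT[c("MEXr", "MEXs")] <- c(0.28, 0.30)
  sigmaT[c("VEN2m", "VEN2s")] <- c(1.7, 1.6)
  phiT[c("VEN2m", "VEN2s")] <- c(0.62, 0.60)

  sigmaV <- stats::runif(n_long, 2.0, 3.5)
  phiV <- stats::runif(n_long, 0.2, 0.5)
  names(sigmaV) <- names(phiV) <- long_md$station_id

  weekly <- list()
  cats_T <- stats::setNames(rep("none", n_long), long_md$station_id)
  cats_V <- stats::setNames(rep(NA_character_, n_long), long_md$station_id)

  for (i in seq_len(n_long)) {
    sid <- long_md$station_id[i]
    start <- as.Date(paste0(long_md$first[i], "-01"))
    # temperature
    if (sid != no_temperature) {
      om <- 0
      if (sid %in% temp_inc) {
        om <- .plant_omega(sigmaT[sid], phiT[sid], yrs[i]); cats_T[sid] <- "increasing"
      } else if (sid %in% temp_dec) {
        om <- -.plant_omega(sigmaT[sid], phiT[sid], yrs[i]); cats_T[sid] <- "decreasing"
      }
      mu_T <- if (grepl("^BER", sid)) 23 else stats::runif(1, 26.5, 28.5)
      cfgT <- series_sim_config(
        n_months = months[i], mu = mu_T, omega = om,
        beta_sin = c(stats::runif(1, 1.2, 2.2), 0.2),
        beta_cos = c(stats::runif(1, 0.3, 1.0), 0.1),
        phi = phiT[sid], sigma_eps = sigmaT[sid] * sqrt(1 - phiT[sid]^2),
        gap_fraction = gap_fraction, start_date = start,
        variable = "temperature", station_id = sid, seed = NULL)
      weekly[[paste0(sid, "_T")]] <- simulate_weekly_series(cfgT)
    } else {
      cats_T[sid] <- NA_character_
    }
    # visibility (reef and seagrass only)
    if (long_md$habitat[i] != "mangrove") {
      omv <- 0
      cats_V[sid] <- "none"
      if (sid %in% vis_dec) {
        omv <- -.plant_omega(sigmaV[sid], phiV[sid], yrs[i]); cats_V[sid] <- "decreasing"
      } else if (sid %in% vis_inc) {
        omv <- .plant_omega(sigmaV[sid], phiV[sid], yrs[i]); cats_V[sid] <- "increasing"
      }
      base_mu <- if (long_md$habitat[i] == "reef")
        stats::runif(1, 18, 28) else stats::runif(1, 9, 15)
      # keep declining series away from zero Secchi
      mu_V <- max(base_mu, 6 - omv * yrs[i])
      cfgV <- series_sim_config(
        n_months = months[i], mu = mu_V, omega = omv,
        beta_sin = c(0, 0), beta_cos = c(0, 0),
        phi = phiV[sid], sigma_eps = sigmaV[sid] * sqrt(1 - phiV[sid]^2),
        gap_fraction = gap_fraction, start_date = start,
        variable = "secchi", station_id = sid, seed = NULL)
      weekly[[paste0(sid, "_V")]] <- simulate_weekly_series(cfgV)
    }
  }

  # short-record stations: temperature only, no planted trends
  for (j in seq_along(short_ids)) {
    cfgS <- series_sim_config(
      n_months = short_months[j], mu = stats::runif(1, 26.5, 28.5),
      omega = 0, beta_sin = c(1.5, 0), beta_cos = c(0.5, 0),
      phi = 0.4, sigma_eps = 0.6, gap_fraction = 0.05,
      start_date = as.Date("1995-01-01"),
      variable = "temperature", station_id = short_ids[j], seed = NULL)
    weekly[[paste0(short_ids[j], "_T")]] <- simulate_weekly_series(cfgS)
  }

  long <- do.call(rbind, weekly)
  long$variable[long$variable == "visibility"] <- "secchi"
  wide <- stats::reshape(long, idvar = c("station_id", "date"),
                         timevar = "variable", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  for (col in c("temperature", "salinity", "secchi"))
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  wide <- wide[order(wide$station_id, wide$date),
               c("station_id", "date", "temperature", "salinity", "secchi")]
  rownames(wide) <- NULL

  # synthetic covariates, conditional on the planted visibility category
  # (mangroves and the Secchi-only station draw from the 'none' pool)
  cov_cat <- ifelse(is.na(cats_V), "none", cats_V)
  npc <- length(cov_cat)
  draw <- function(cat, dec, inc, none) {
    mu <- ifelse(cat == "decreasing", dec[1],
                 ifelse(cat == "increasing", inc[1], none[1]))
    sd <- ifelse(cat == "decreasing", dec[2],
                 ifelse(cat == "increasing", inc[2], none[2]))
    stats::rnorm(npc, mu, sd)
  }
  covariates <- data.frame(
    station_id = long_md$station_id,
    wave_exposure = pmax(draw(cov_cat, c(450, 300), c(1400, 400),
                              c(850, 350)), 10),
    current_speed = pmax(draw(cov_cat, c(0.11, 0.06), c(0.32, 0.09),
                              c(0.20, 0.07)), 0.005),
    delta_population = draw(cov_cat, c(3.3e5, 1.2e5), c(5e4, 4e4),
                            c(1.6e5, 9e4)),
    rainfall_trend = draw(cov_cat, c(0.55, 0.35), c(-0.55, 0.35),
                          c(0, 0.35)),
    stringsAsFactors = FALSE)
  # population grew everywhere except Bonaire
  covariates$delta_population <- abs(covariates$delta_population)
  covariates$delta_population[covariates$station_id == "BONr"] <-
    -abs(stats::rnorm(1, 2e3, 1e3))

  list(weekly = wide, metadata = metadata, covariates = covariates,
       true_categories = list(temperature = cats_T[!is.na(cats_T)],
                              visibility = cats_V[!is.na(cats_V)]))
}
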