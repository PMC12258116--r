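# Independent oracles, kept deliberately separate from the package's own code
# paths: a direct recurrence for total cell counts and a stats::uniroot-based
# root finder (the package uses bisection).

# N(t) = N(t-1) + N(t-c), N(t) = t + 1 for t <= c
oracle_total_cells <- function(c, T) {
  N <- numeric(T + 1)
  for (t in 0:T) N[t + 1] <- if (t <= c) t + 1 else N[t] + N[t + 1 - c]
  N
}

oracle_lambda <- function(c) {
  if (c == 1) return(1)
  uniroot(function(x) x * (1 + x)^(c - 1) - 1, c(1e-12, 1), tol = 1e-14)$root
}

oracle_rho <- function(c) {
  if (c == 1) return(2)
  uniroot(function(x) x^c - x^(c - 1) - 1, c(1 + 1e-12, 2), tol = 1e-14)$root
}

# horizons keeping per-cell simulations comfortably small for fast-growing c
sim_horizon <- function(c) c(14, 20, 25, 30, 30, 30, 30, 30)[min(c, 8)]

# spatial runs pay for displacement chains too; keep populations ~1e3
rosette_horizon <- function(c) c(9, 12, 15, 16, 18, 18, 18, 18)[min(c, 8)]

# Table 3 as printed (c, k1, k2, lambda1, M/I), frozen to 6 decimals
table3_printed <- data.frame(
  c = 1:6,
  k1 = 1,
  k2      = c(1, 0.381966, 0.216757, 0.144611, 0.105442, 0.081338),
  lambda1 = c(1, 0.618034, 0.465571, 0.380278, 0.324718, 0.285199),
  M_over_I = c(1, 0.618034, 0.465571, 0.380278, 0.324718, 0.285199)
)

# Table 2: order of cell divisions for c = 6 ("parent>child"; row 15 printed
# "5→50", an evident misnumbering for 5→60 — the label sequence is forced)
table2_events <- list(
  `1` = "0>1", `2` = "0>2", `3` = "0>3", `4` = "0>4", `5` = "0>5",
  `6` = "0>6",
  `7` = c("0>7", "1>8"),
  `8` = c("0>9", "1>10", "2>11"),
  `9` = c("0>12", "1>13", "2>14", "3>15"),
  `10` = c("0>16", "1>17", "2>18", "3>19", "4>20"),
  `11` = c("0>21", "1>22", "2>23", "3>24", "4>25", "5>26"),
  `12` = c("0>27", "1>28", "2>29", "3>30", "4>31", "5>32", "6>33"),
  `13` = c("0>34", "1>35", "2>36", "3>37", "4>38", "5>39", "6>40", "7>41",
           "8>42"),
  `14` = c("0>43", "1>44", "2>45", "3>46", "4>47", "5>48", "6>49", "7>50",
           "8>51", "9>52", "10>53", "11>54"),
  `15` = c("0>55", "1>56", "2>57", "3>58", "4>59", "5>60", "6>61", "7>62",
           "8>63", "9>64", "10>65", "11>66", "12>67", "13>68", "14>69",
           "15>70")
)
table2_cells <- c(1, 2, 3, 4, 5, 6, 7, 9, 12, 16, 21, 27, 34, 43, 55, 71)
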