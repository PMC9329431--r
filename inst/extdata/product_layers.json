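[
  {
    "name": "NumCycles",
    "description": "Number of phenological cycles detected in target year",
    "units": "Number of cycles",
    "scale_factor": 1,
    "valid_min": 0,
    "valid_max": 6,
    "fill": 32767
  },
  {
    "name": "OGI",
    "description": "Onset Greenness Increase (Date of 15% greenness increase)",
    "units": "Day of year (January 1 of target year = 1)",
    "scale_factor": 1,
    "valid_min": -181,
    "valid_max": 548,
    "fill": 32767
  },
  {
    "name": "50PCGI",
    "description": "50 Percent Greenness Increase (Date of 50% greenness increase)",
    "units": "Day of year (January 1 of target year = 1)",
    "scale_factor": 1,
    "valid_min": -181,
    "valid_max": 548,
    "fill": 32767
  },
  {
    "name": "OGMx",
    "description": "Onset Greenness Maximum (Date of 90% greenness increase)",
    "units": "Day of year (January 1 of target year = 1)",
    "scale_factor": 1,
    "valid_min": -181,
    "valid_max": 548,
    "fill": 32767
  },
  {
    "name": "Peak",
    "description": "Date of Cycle Peak",
    "units": "Day of year (January 1 of target year = 1)",
    "scale_factor": 1,
    "valid_min": 1,
    "valid_max": 366,
    "fill": 32767
  },
  {
    "name": "OGD",
    "description": "Onset Greenness Decrease (Date of 10% greenness decrease)",
    "units": "Day of year (January 1 of target year = 1)",
    "scale_factor": 1,
    "valid_min": -181,
    "valid_max": 548,
    "fill": 32767
  },
  {
    "name": "50PCGD",
    "description": "50 Percent Greenness Decrease (Date of 50% greenness decrease)",
    "units": "Day of year (January 1 of target year = 1)",
    "scale_factor": 1,
    "valid_min": -181,
    "valid_max": 548,
    "fill": 32767
  },
  {
    "name": "OGMn",
    "description": "Onset Greenness Minimum (Date of 85% greenness decrease)",
    "units": "Day of year (January 1 of target year = 1)",
    "scale_factor": 1,
    "valid_min": -181,
    "valid_max": 548,
    "fill": 32767
  },
  {
    "name": "EVImax",
    "description": "Maximum EVI2 during vegetation cycle",
    "units": "-",
    "scale_factor": 0.0001,
    "valid_min": 0,
    "valid_max": 10000,
    "fill": 32767
  },
  {
    "name": "EVIamp",
    "description": "EVI2 Amplitude during vegetation cycle",
    "units": "-",
    "scale_factor": 0.0001,
    "valid_min": 0,
    "valid_max": 10000,
    "fill": 32767
  },
  {
    "name": "EVIarea",
    "description": "Integrated EVI2 during vegetation cycle",
    "units": "-",
    "scale_factor": 0.01,
    "valid_min": 0,
    "valid_max": 32766,
    "fill": 32767
  },
  {
    "name": "OGI_2",
    "description": "Onset Greenness Increase (Date of 15% greenness increase)",
    "units": "Day of year (January 1 of target year = 1)",
    "scale_factor": 1,
    "valid_min": -181,
    "valid_max": 548,
    "fill": 32767
  },
  {
    "name": "50PCGI_2",
    "description": "50 Percent Greenness Increase (Date of 50% greenness increase)",
    "units": "Day of year (January 1 of target year = 1)",
    "scale_factor": 1,
    "valid_min": -181,
    "valid_max": 548,
    "fill": 32767
  },
  {
    "name": "OGMx_2",
    "description": "Onset Greenness Maximum (Date of 90% greenness increase)",
    "units": "Day of year (January 1 of target year = 1)",
    "scale_factor": 1,
    "valid_min": -181,
    "valid_max": 548,
    "fill": 32767
  },
  {
    "name": "Peak_2",
    "description": "Date of Cycle Peak",
    "units": "Day of year (January 1 of target year = 1)",
    "scale_factor": 1,
    "valid_min": 1,
    "valid_max": 366,
    "fill": 32767
  },
  {
    "name": "OGD_2",
    "description": "Onset Greenness Decrease (Date of 10% greenness decrease)",
    "units": "Day of year (January 1 of target year = 1)",
    "scale_factor": 1,
    "valid_min": -181,
    "valid_max": 548,
    "fill": 32767
  },
  {
    "name": "50PCGD_2",
    "description": "50 Percent Greenness Decrease (Date of 50% greenness decrease)",
    "units": "Day of year (January 1 of target year = 1)",
    "scale_factor": 1,
    "valid_min": -181,
    "valid_max": 548,
    "fill": 32767
  },
  {
    "name": "OGMn_2",
    "description": "Onset Greenness Minimum (Date of 85% greenness decrease)",
    "units": "Day of year (January 1 of target year = 1)",
    "scale_factor": 1,
    "valid_min": -181,
    "valid_max": 548,
    "fill": 32767
  },
  {
    "name": "EVImax_2",
    "description": "Maximum EVI2 during vegetation cycle",
    "units": "-",
    "scale_factor": 0.0001,
    "valid_min": 0,
    "valid_max": 10000,
    "fill": 32767
  },
  {
    "name": "EVIamp_2",
    "description": "EVI2 Amplitude during vegetation cycle",
    "units": "-",
    "scale_factor": 0.0001,
    "valid_min": 0,
    "valid_max": 10000,
    "fill": 32767
  },
  {
    "name": "EVIarea_2",
    "description": "Integrated EVI2 during vegetation cycle",
    "units": "-",
    "scale_factor": 0.01,
    "valid_min": 0,
    "valid_max": 32766,
    "fill": 32767
  },
  {
    "name": "QA",
    "description": "Quality Assurance for first vegetation cycle",
    "units": "-",
    "scale_factor": 1,
    "valid_min": 1,
    "valid_max": 4,
    "fill": null
  },
  {
    "name": "QA_2",
    "description": "Quality Assurance for second vegetation cycle",
    "units": "-",
    "scale_factor": 1,
    "valid_min": 1,
    "valid_max": 4,
    "fill": null
  },
  {
    "name": "numObs",
    "description": "Number of days with clear observations in calendar year",
    "units": "Days",
    "scale_factor": 1,
    "valid_min": 0,
    "valid_max": 366,
    "fill": 32767
  }
]
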