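policy: dedicated
p_new: 0.0
ticket_close: '14:50'
arrivals:
- start: '05:00'
  end: '06:00'
  shift_min: 0.0
  mean_min: 10.0
- start: '06:00'
  end: '10:30'
  shift_min: 0.5
  mean_min: 1.24
- start: '10:30'
  end: '15:00'
  shift_min: 0.0
  mean_min: 2.67
type_mix:
- start: '05:00'
  end: '07:00'
  probs:
  - 0.36
  - 0.1
  - 0.08
  - 0.46
- start: '07:00'
  end: '09:00'
  probs:
  - 0.35
  - 0.1
  - 0.11
  - 0.44
- start: '09:00'
  end: '11:00'
  probs:
  - 0.27
  - 0.09
  - 0.1
  - 0.54
- start: '11:00'
  end: '13:00'
  probs:
  - 0.26
  - 0.1
  - 0.1
  - 0.54
- start: '13:00'
  end: '15:00'
  probs:
  - 0.26
  - 0.1
  - 0.1
  - 0.54
services:
  blood_pressure:
    family: constant
    value: 49.0
  triage:
    family: shifted_exponential
    shift: 25.0
    mean: 71.2
  fill_info:
    family: constant
    value: 300.0
  mr_type1:
    family: shifted_weibull
    shift: 14.0
    scale: 47.4
    shape: 0.94
  mr_type2:
    family: shifted_weibull
    shift: 14.0
    scale: 47.4
    shape: 0.94
  mr_type3:
    family: triangular
    min: 84.0
    mode: 146.8
    max: 251.0
  mr_type4:
    family: triangular
    min: 59.0
    mode: 72.8
    max: 197.0
satisfaction:
  '1':
    los:
    - 55.0
    - 90.0
    - 120.0
    score:
    - 100.0
    - 75.0
    - 50.0
  '2':
    los:
    - 15.0
    - 30.0
    - 60.0
    score:
    - 100.0
    - 75.0
    - 50.0
  '3':
    los:
    - 45.0
    - 70.0
    - 90.0
    score:
    - 100.0
    - 75.0
    - 50.0
  '4':
    los:
    - 45.0
    - 70.0
    - 90.0
    score:
    - 100.0
    - 75.0
    - 50.0
weights:
- - 0.8
  - 0.2
- - 0.2
  - 0.8
- - 0.6
  - 0.4
- - 0.4
  - 0.6
- - 0.5
  - 0.5
schedule:
  periods:
  - 07-09
  - 09-11
  - 11-13
  - 13-15
  rows:
    'N':
    - 6
    - 6
    - 6
    - 6
    N2:
    - 3
    - 3
    - 3
    - 3
    M:
    - 0
    - 0
    - 0
    - 0
    M1:
    - 3
    - 3
    - 3
    - 3
    M12:
    - 0
    - 0
    - 0
    - 0
    M2:
    - 3
    - 3
    - 3
    - 3
    M3:
    - 2
    - 2
    - 2
    - 2
    M4:
    - 10
    - 10
    - 10
    - 10
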