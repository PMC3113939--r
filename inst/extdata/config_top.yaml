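schema: 1
id: default-top
view: top
mm_per_px: 1.0
region_scale: 1.0
opening_radius: 1
regions:
- name: soil
  shape: circle
  geometry:
  - 99.5
  - 99.5
  - 60.0
- name: carrier
  shape: rectangle
  geometry:
  - 12.0
  - 12.0
  - 187.0
  - 187.0
- name: cages
  shape: rectangle
  geometry:
  - 0.0
  - 70.0
  - 10.0
  - 130.0
- name: sticks
  shape: rectangle
  geometry:
  - 190.0
  - 70.0
  - 199.0
  - 130.0
- name: conveyor_belt
  shape: rectangle
  geometry:
  - 0.0
  - 186.0
  - 199.0
  - 199.0
classes:
- name: soil
  display_colour:
  - 139.0
  - 90.0
  - 43.0
  region: soil
  profiles:
  - h_unit: degrees
    R:
    - 110.0
    - 130.0
    G:
    - 75.0
    - 95.0
    B:
    - 30.0
    - 50.0
    H:
    - 18.750000000000004
    - 48.75
    S:
    - 0.545454545454546
    - 0.769230769230769
    V:
    - 0.431372549019608
    - 0.509803921568627
- name: carrier
  display_colour:
  - 0.0
  - 0.0
  - 255.0
  region: carrier
  profiles:
  - h_unit: degrees
    R:
    - 60.0
    - 80.0
    G:
    - 85.0
    - 105.0
    B:
    - 155.0
    - 175.0
    H:
    - 211.578947368421041
    - 236.842105263157862
    S:
    - 0.483870967741935
    - 0.657142857142857
    V:
    - 0.607843137254902
    - 0.686274509803922
- name: cages
  display_colour:
  - 255.0
  - 0.0
  - 255.0
  region: cages
  profiles:
  - h_unit: degrees
    R:
    - 180.0
    - 200.0
    G:
    - 50.0
    - 70.0
    B:
    - 165.0
    - 185.0
    H:
    - 297.391304347826065
    - 316.153846153846132
    S:
    - 0.611111111111111
    - 0.75
    V:
    - 0.705882352941177
    - 0.784313725490196
- name: sticks
  display_colour:
  - 70.0
  - 70.0
  - 255.0
  region: sticks
  profiles:
  - h_unit: degrees
    R:
    - 30.0
    - 50.0
    G:
    - 50.0
    - 70.0
    B:
    - 110.0
    - 130.0
    H:
    - 210.0
    - 240.0
    S:
    - 0.545454545454546
    - 0.769230769230769
    V:
    - 0.431372549019608
    - 0.509803921568627
- name: conveyor_belt
  display_colour:
  - 0.0
  - 0.0
  - 0.0
  region: conveyor_belt
  profiles:
  - h_unit: degrees
    R:
    - 25.0
    - 45.0
    G:
    - 25.0
    - 45.0
    B:
    - 25.0
    - 45.0
    H:
    - 183.000000000000028
    - 180.0
    S:
    - 0.0
    - 0.444444444444444
    V:
    - 0.098039215686275
    - 0.176470588235294
- name: plant
  display_colour:
  - 0.0
  - 255.0
  - 0.0
  profiles:
  - h_unit: degrees
    R:
    - 45.0
    - 65.0
    G:
    - 155.0
    - 175.0
    B:
    - 50.0
    - 70.0
    H:
    - 111.428571428571431
    - 133.636363636363654
    S:
    - 0.580645161290323
    - 0.742857142857143
    V:
    - 0.607843137254902
    - 0.686274509803922
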