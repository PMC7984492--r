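checklist_name,stat,technique,total_minutes
TG315_full,max,IMRT_VMAT,66.5
TG315_full,max,THREE_D,55.5
TG315_full,max,SIMPLE_2D,50.5
TG315_full,median,IMRT_VMAT,50.3
TG315_full,median,THREE_D,44.6
TG315_full,median,SIMPLE_2D,19.1
TG315_full,min,IMRT_VMAT,8.8
TG315_full,min,THREE_D,9.2
TG315_full,min,SIMPLE_2D,9.9
TG275_full,max,IMRT_VMAT,185.5
TG275_full,max,THREE_D,133.0
TG275_full,max,SIMPLE_2D,95.0
TG275_full,median,IMRT_VMAT,72.8
TG275_full,median,THREE_D,71.8
TG275_full,median,SIMPLE_2D,37.1
TG275_full,min,IMRT_VMAT,36.5
TG275_full,min,THREE_D,34.6
TG275_full,min,SIMPLE_2D,16.0
TG315_recommended,max,IMRT_VMAT,51.9
TG315_recommended,max,THREE_D,47.7
TG315_recommended,max,SIMPLE_2D,36.9
TG315_recommended,median,IMRT_VMAT,42.2
TG315_recommended,median,THREE_D,37.6
TG315_recommended,median,SIMPLE_2D,17.0
TG315_recommended,min,IMRT_VMAT,6.1
TG315_recommended,min,THREE_D,6.6
TG315_recommended,min,SIMPLE_2D,7.8
TG275_priority,max,IMRT_VMAT,144.6
TG275_priority,max,THREE_D,91.1
TG275_priority,max,SIMPLE_2D,62.6
TG275_priority,median,IMRT_VMAT,48.1
TG275_priority,median,THREE_D,47.1
TG275_priority,median,SIMPLE_2D,21.0
TG275_priority,min,IMRT_VMAT,23.0
TG275_priority,min,THREE_D,22.5
TG275_priority,min,SIMPLE_2D,3.5
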